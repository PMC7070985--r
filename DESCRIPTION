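Package: emg3d
Title: High-Density Surface EMG Gesture Recognition with 3D Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for gesture recognition from high-density
    surface electromyography (HD-sEMG) electrode grids. Raw multi-channel
    recordings are conditioned with zero-phase Butterworth filtering, muscle
    activity is segmented from the rectified intensity envelope, instantaneous
    sEMG images are stacked into spatiotemporal cubes, and a 3D convolutional
    neural network (with a 2D ablation) classifies gestures, optionally
    combined with sliding-window majority voting. Includes a synthetic
    HD-sEMG generator emulating static and dynamic gesture content so the
    whole pipeline runs with no external data, analytic parameter counting
    for the network architectures, and desk-scale experiment protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rhdf5,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
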