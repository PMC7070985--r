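---
title: "Methods: spatiotemporal gesture recognition from HD-sEMG grids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal gesture recognition from HD-sEMG grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

High-density surface EMG (HD-sEMG) replaces a handful of bipolar electrodes
with a dense 2D grid, so the recording at each time frame can be arranged as
a grayscale *instantaneous sEMG image* whose pixels are electrode channels.
A gesture then appears as a short video: a spatial activation pattern that
evolves over tens to hundreds of milliseconds. `emg3d` classifies stacks of
`l` consecutive images ("cubes", `l × h × w × 1`) with a 3D convolutional
network whose kernels extend over both space and time, and compares it with
the spatial-only alternative — a 2D network on single images combined with
majority voting over consecutive frame predictions. The scientific question
the package's experiments address is when the extra temporal structure
helps: for static holds a single image already carries the class, while for
dynamic gestures the label lives partly in how the image moves.

The classifier is deliberately plain. Three convolution layers
(32/64/64 kernels of 3 × 3 × 3, stride 1 × 1 × 1) with zero padding
0 × 1 × 1 on the second and third, each of those followed by a temporal max
pooling of `s × 1 × 1` (sub-sampling only in time; `s = 2` for 1000 Hz
grids, `s = 4` for 2048 Hz), then dense layers of 512 and 128 units and a
G-way softmax. Batch normalization precedes every ReLU; dropout
(p = 0.5) regularizes the two hidden dense layers. Training is plain
minibatch SGD on the categorical cross-entropy with initial learning rate
0.1, halved whenever the epoch loss fails to improve for 10 consecutive
epochs. The 2D ablation removes the temporal extent of kernels, padding and
pooling and keeps everything else, so any performance gap is attributable
to the form of convolution, not to capacity or depth.

The binary form of the cross-entropy is provided as
`binary_cross_entropy()` for two-class problems; the trainer itself uses the
multi-class generalization over the softmax, which reduces to it at G = 2.

## Numerical choices

**Convolution.** The trainable layer is an im2col/GEMM implementation (C++,
single-threaded); `conv3d_reference()` is an independent nested-loop
evaluation of the defining summation. The two must agree to 1e-5 across
random shapes — this dual-route check is part of the test suite, as is a
finite-difference validation of every gradient.

**Pooling semantics.** The temporal pooling uses windows of size `s`,
stride `s`, and a boundary-truncated final window (output length
`ceil(l / s)`). Floor semantics would annihilate the temporal dimension for
the shortest useful cubes (e.g. `l = 10` with two poolings of 2:
10 → 8 → 6 → 3 → 1), so size-1 survivors are kept. Pooling is attached
after the second and the third convolution.

**Zero-phase filtering.** Muscle-activity timing must not be shifted by
conditioning, so all filtering is zero-phase. Rather than approximating the
forward–backward pass with reflective padding — whose edge transients at a
20 Hz high-pass edge and 2048 Hz sampling decay over hundreds of samples and
visibly break time-reversal symmetry — the package applies the Butterworth
squared-magnitude response exactly in the frequency domain, on an even
(mirrored) extension of each channel. This realizes the same pass-band gain
as a forward–backward filter, has identically zero phase, and commutes with
time reversal to machine precision (a property the test suite asserts).
`order = 4` follows the MATLAB/scipy convention: the band-pass prototype of
order 4 has 8 poles.

**Segmentation rule.** The intensity envelope (|x| then 4 Hz zero-phase
low-pass, negative ringing clamped at 0) is cut into non-overlapping windows
of 150 frames (73.2 ms at 2048 Hz); a window is active when the sum over
channels of its mean intensity strictly exceeds the mean of that statistic
over all windows. Ties at the threshold count as inactive, a trailing
partial window is discarded, and the *longest contiguous run* of active
windows is returned — one gesture per 3 s trial implies a single dominant
burst, and strictness makes the all-constant envelope degenerate case an
explicit "no activity detected" error rather than an arbitrary segment.
Multiple disjoint bursts are deliberately not merged; only the dominant one
is kept.

**Majority voting.** Voting windows are non-overlapping and never span
trial boundaries; trailing cubes that do not fill a window are dropped. The
vote returns the modal label, and exact ties resolve to the tied label whose
most recent occurrence is latest — in an online setting the newest evidence
is the most relevant. With one cube per window the voted accuracy equals the
per-cube accuracy exactly (a test invariant), and for i.i.d. per-cube errors
the voted error follows the binomial tail, which the suite checks against
the closed form. Both the one-decision-per-window accuracy (the headline
number) and the per-window fraction of correct cubes are reported. Windows
longer than 300 ms — the conventional real-time bound for prosthesis
control — trigger a warning rather than an error, because desk-scale
experiments legitimately explore beyond it.

**Tie-breaking in argmax.** Softmax predictions resolve exact probability
ties to the smallest class index; probabilities sum to one within 1e-6.

**Parameter counting.** `count_parameters()` is analytic (no tensors are
instantiated) and must equal an exhaustive enumeration of the instantiated
model's arrays under every convention tag — `"trainable"` counts
convolution/dense weights and biases plus the batch-normalization scale and
shift (2 per channel); `"with-statistics"` adds the running mean and
variance (4 per channel), which is what a Keras-style total-parameter
summary prints; `"none"` ignores batch normalization. Published totals for
this architecture family are reproduced to within about 1–5% but not at
3-significant-figure precision under any convention we enumerated
(including padding variants, pooling placement and boundary semantics,
bias inclusion, and the frames-vs-ms reading of window lengths); the
acceptance script therefore reports the honestly computed counts under the
documented `"with-statistics"` convention.

## The synthetic generator

The generator emulates the statistical structure the pipeline assumes, not
EMG physiology. Each trial is rest–activity–rest: a raised-cosine-ramped
envelope (ramps of 10% of the active duration, so the 4 Hz intensity filter
can track them) occupies a configured fraction of the trial (default the
middle third of 3 s). Within the activity, each channel receives the product
of the envelope, a per-gesture spatial weight, and a per-channel carrier —
Gaussian white noise band-passed to 20–400 Hz and standardized, matching the
band the preprocessing assumes. Baseline white noise is added at a
configured plateau SNR (default 20 dB; the end-to-end benchmarks use a
harder 10 dB). Per-trial RNG streams derive from
`(master seed, gesture, trial)`, so datasets are reproducible regardless of
generation order. Ten trials per gesture mirror the benchmark databases'
trial structure.

**Static gestures** are isotropic Gaussian bumps (σ = 1.5 px) at
farthest-point-placed centers — for four gestures on an 8 × 16 grid the
pairwise center distance is at least 3 px, so instantaneous images are
separable and even a nearest-template frame classifier is far above chance
(a property test).

**Dynamic gestures** come in pairs sharing one center and drifting along
the grid columns with opposite velocities (default 4 px/s). The drift path
is translated by a random per-trial offset, so over a trial both members of
a pair sweep the same position interval with the same dwell-time
distribution: a single frame carries (almost) no label information within a
pair, and the label lives in the *displacement* across consecutive frames.
Two designs that look equivalent are not: un-randomized opposite drifts
separate the two gestures' position sets (single frames leak the label),
and drifts reflected at the grid margins make the two trajectories
time-shifted copies of one triangle wave (identical cube distributions — no
information at all, not even temporal). A subtler alternative, clockwise
versus counter-clockwise orbits, keeps single frames uninformative but
makes the direction a purely second-order (motion-energy) statistic, which
is measurably recoverable yet far too sample-hungry for a desk-scale
network; the randomized linear drift keeps the direction first-order
(a late-minus-early centroid difference) and therefore learnable at this
scale.

What the generator does *not* model — motor-unit action potentials,
electrode-skin impedance variation, electrode shift, fatigue, crosstalk,
inter-subject variability — bounds what passing benchmarks show: they
validate the pipeline's mechanics and the spatial-versus-spatiotemporal
contrast, not recognition rates on real muscle.

## The desk-scale benchmarks

Two frozen configurations (`static_benchmark_config()`,
`dynamic_benchmark_config()`) define the package's end-to-end experiments;
both run on one CPU core in minutes.

* **Static**: 4 gestures, 8 × 16 grid at 1000 Hz, 3 s trials with 1 s of
  activity, 10 dB SNR, 10 trials/gesture, half-half trial split, 10-frame
  cubes (training stride 25), a scaled-down network (8/16/16 kernels,
  64/32 dense), 15 epochs. The target is ≥ 90% voted accuracy; spatial
  information suffices, and both the 3D network and the 2D ablation should
  approach the ceiling.
* **Dynamic**: 4 gestures in two drift pairs, 8 × 16 grid at 256 Hz with a
  20–100 Hz carrier, 4 s trials with 2 s of activity, 10 dB SNR,
  10 trials/gesture, 128-frame cubes (500 ms; training stride 8), a 4/8/8
  kernel network with 32/16 dense layers and no dropout, 15 epochs at
  learning rate 0.05. Here single-frame classification is capped at 50%
  (it can identify the pair, never the direction), so the measured contrast
  is the 3D network's per-cube accuracy against the 2D + voting ablation
  over the same time span.

Scaling decisions worth recording: the dynamic benchmark's sampling rate
(256 Hz) and drift speed (4 px/s — slow enough that the path stays on a
16-column grid for 2 s) set the time scale of the motion, and the cube must
span enough of it to make the displacement (2 px per 500 ms cube) resolve
against the carrier noise; this knowingly exceeds the 300 ms real-time bound
(the evaluator warns) and is accepted as a property of the synthetic motion
being slower than real finger dynamics. Dropout is disabled in the dynamic
benchmark's scaled-down dense layers (32/16 units), where p = 0.5 removes
half of an already tiny representation, and the learning rate is halved to
0.05, which stabilizes plain SGD on this harder objective; the full-size
architecture keeps the standard p = 0.5 and rate 0.1. The problem sizes (trials, epochs, kernel counts) are
chosen so the whole pipeline — generation, filtering, segmentation, two
trainings, evaluation — is a coffee-break computation; accuracies are
correspondingly noisier than a GPU-scale study and only the direction of
the 3D-vs-2D contrast, not its magnitude, is the claim.

## Known limitations

* The trainer is a minimal SGD implementation (no momentum, no weight
  decay, no data loaders); it is meant for desk-scale validation, not
  large-scale training.
* Leave-one-trial-out evaluation retrains per fold and is correspondingly
  slow; the default experiment uses the half-half protocol.
* The MATLAB v5 container adapter for the public benchmark databases is not
  included; recordings arrive via HDF5, NPY or CSV.
* Batch-normalization inference statistics come from a running average with
  momentum 0.9; with very few training batches they are noisy, which mildly
  penalizes small experiments.
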