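test_that("static templates have well-separated centers and normalized maps", {
  cfg <- synth_config(G = 4, grid = electrode_grid(8, 16), seed = 1)
  tms <- make_gesture_templates(cfg)
  expect_length(tms, 4)
  centers <- t(vapply(tms, `[[`, numeric(2), "center"))
  d <- as.matrix(dist(centers))
  expect_gte(min(d[upper.tri(d)]), 3)
  for (tm in tms) {
    expect_equal(sum(tm$spatial_map), 1)
    expect_equal(tm$drift, c(0, 0))
  }
  # deterministic: same configuration, same templates
  expect_identical(tms, make_gesture_templates(cfg))
})

test_that("dynamic templates pair identical maps with opposite motion", {
  cfg <- synth_config(G = 4, grid = electrode_grid(8, 16), fs = 256,
                      carrier_band = c(20, 100), seed = 1)
  tms <- make_gesture_templates(cfg, dynamic = TRUE)
  expect_equal(tms[[1]]$spatial_map, tms[[2]]$spatial_map)
  expect_equal(tms[[1]]$drift, -tms[[2]]$drift)
  expect_true(any(tms[[1]]$drift != 0))
  expect_false(isTRUE(all.equal(tms[[1]]$spatial_map, tms[[3]]$spatial_map)))
})

test_that("a grid too small for the requested gestures is an error", {
  cfg <- synth_config(G = 200, grid = electrode_grid(3, 3), seed = 1)
  expect_error(make_gesture_templates(cfg), "too small")
})

test_that("simulated trials are reproducible and carry ground truth", {
  cfg <- synth_config(G = 2, grid = tiny_grid(), fs = 1000, trial_s = 1,
                      n_trials_per_gesture = 2, seed = 5)
  tm <- make_gesture_templates(cfg)[[1]]
  r1 <- simulate_trial(tm, cfg, trial_idx = 1L)
  r2 <- simulate_trial(tm, cfg, trial_idx = 1L)
  expect_identical(r1$signal, r2$signal)
  r3 <- simulate_trial(tm, cfg, trial_idx = 0L)
  expect_false(identical(r1$signal, r3$signal))
  expect_equal(r1$meta$onset_frame, round(1000 / 3))
})

test_that("zero-amplitude trials contain no detectable activity", {
  cfg <- synth_config(G = 2, grid = electrode_grid(4, 4), fs = 1000,
                      trial_s = 2, seed = 2)
  tm <- make_gesture_templates(cfg)[[1]]
  tm$amplitude <- 0
  rec <- simulate_trial(tm, cfg)
  env <- intensity_envelope(rec$signal, cfg$fs)
  expect_error(segment_activity(env, 150L), "no activity detected")
})

test_that("active-portion spectral mass is concentrated in the carrier band", {
  cfg <- synth_config(G = 2, grid = electrode_grid(4, 4), fs = 2048,
                      trial_s = 2, snr_db = 30, seed = 3)
  tm <- make_gesture_templates(cfg)[[1]]
  rec <- simulate_trial(tm, cfg)
  act <- (rec$meta$onset_frame + 100):(rec$meta$offset_frame - 100)
  # channel nearest the activation center carries the band-limited carrier
  ch <- which.max(tm$spatial_map)
  sp <- stats::spec.pgram(rec$signal[ch, act], taper = 0, plot = FALSE)
  freq_hz <- sp$freq * cfg$fs
  inband <- freq_hz >= 20 & freq_hz <= 400
  expect_gt(sum(sp$spec[inband]) / sum(sp$spec), 0.9)
  # carrier above Nyquist is rejected up front
  expect_error(synth_config(fs = 500, carrier_band = c(20, 400)), "Nyquist")
})

test_that("benchmarks are balanced and reproducible", {
  cfg <- synth_config(G = 4, grid = electrode_grid(4, 6), fs = 1000,
                      trial_s = 1, n_trials_per_gesture = 3, seed = 7)
  b1 <- make_benchmark(cfg)
  expect_length(b1, 12)
  labs <- vapply(b1, function(r) r$meta$gesture, integer(1))
  expect_equal(as.vector(table(labs)), rep(3L, 4))
  b2 <- make_benchmark(cfg)
  expect_identical(lapply(b1, `[[`, "signal"), lapply(b2, `[[`, "signal"))
})

test_that("synthetic data passes the full preprocessing chain for both geometries", {
  for (geo in list(list(grid = electrode_grid(8, 16), fs = 1000, band = c(20, 400)),
                   list(grid = electrode_grid(7, 24), fs = 2048, band = c(20, 400)))) {
    cfg <- synth_config(G = 2, grid = geo$grid, fs = geo$fs, trial_s = 2,
                        n_trials_per_gesture = 1, seed = 11)
    rec <- make_benchmark(cfg)[[1]]
    s <- prepare_sequence(rec, style = "csl", band = geo$band, window_len = 150L)
    expect_s3_class(s, "image_sequence")
    expect_true(all(s$frames >= 0 & s$frames <= 1))
    expect_equal(dim(s$frames)[2:3], c(geo$grid$rows, geo$grid$cols))
  }
})

test_that("segmentation recovers the known activity interval at high SNR", {
  cfg <- synth_config(G = 2, grid = electrode_grid(7, 24), fs = 2048,
                      trial_s = 3, snr_db = 20, n_trials_per_gesture = 3,
                      seed = 13)
  tms <- make_gesture_templates(cfg)
  for (tm in tms) for (tr in 0:2) {
    rec <- simulate_trial(tm, cfg, tr)
    filt <- bandpass_zero_lag(rec$signal, cfg$fs)
    seg <- segment_activity(intensity_envelope(filt, cfg$fs), 150L)
    expect_lte(abs(seg$start_frame - rec$meta$onset_frame), 150)
    expect_lte(abs(seg$end_frame - rec$meta$offset_frame), 150)
  }
})

test_that("the spatial baseline separates static gestures but not orbit pairs", {
  cfg_s <- synth_config(G = 4, grid = electrode_grid(8, 16), fs = 1000,
                        trial_s = 1.5, snr_db = 15, n_trials_per_gesture = 3,
                        seed = 17)
  tms <- make_gesture_templates(cfg_s)
  seqs <- lapply(make_benchmark(cfg_s), prepare_sequence, style = "csl",
                 window_len = 100L)
  acc_static <- nearest_template_baseline(seqs, tms, cfg_s$grid)
  expect_gt(acc_static, 50)  # chance is 25%
  cfg_d <- synth_config(G = 2, grid = electrode_grid(8, 16), fs = 256,
                        trial_s = 3, carrier_band = c(20, 100), snr_db = 15,
                        n_trials_per_gesture = 6, seed = 19)
  tms_d <- make_gesture_templates(cfg_d, dynamic = TRUE)
  seqs_d <- lapply(make_benchmark(cfg_d, dynamic = TRUE), prepare_sequence,
                   style = "csl", band = c(20, 100), window_len = 64L)
  acc_dyn <- nearest_template_baseline(seqs_d, tms_d, cfg_d$grid)
  # the pair shares its center: a single-frame classifier is at chance
  expect_lt(acc_dyn, 85)
  expect_equal(tms_d[[1]]$spatial_map, tms_d[[2]]$spatial_map)
})

test_that("benchmark manifests list trials with ground truth", {
  cfg <- synth_config(G = 2, grid = electrode_grid(4, 4), fs = 1000,
                      trial_s = 1, n_trials_per_gesture = 2, seed = 23)
  trials <- make_benchmark(cfg)
  path <- tempfile(fileext = ".csv")
  write_manifest(trials, path)
  mf <- read.csv(path)
  expect_equal(nrow(mf), 4)
  expect_equal(sort(unique(mf$gesture)), 0:1)
  expect_true(all(mf$offset_frame > mf$onset_frame))
  unlink(path)
})
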