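test_that("unit-interval normalization is the clipped affine map", {
  expect_equal(normalize_unit_interval(c(-1, 0, 1), c(-1, 1)), c(0, 0.5, 1))
  expect_equal(normalize_unit_interval(matrix(2, 3, 4), c(2, 5)),
               matrix(0, 3, 4))
  set.seed(1)
  x <- matrix(rnorm(200), 10)
  y <- normalize_unit_interval(x)
  expect_equal(min(y), 0)
  expect_equal(max(y), 1)
  expect_true(all(y >= 0 & y <= 1))
  # clipping outside the declared range
  expect_equal(normalize_unit_interval(c(-5, 5), c(-1, 1)), c(0, 1))
  expect_error(normalize_unit_interval(1:3, c(2, 2)), "degenerate")
})

test_that("band-pass filtering is zero-phase and removes DC", {
  expect_equal(bandpass_zero_lag(numeric(2048), 2048), numeric(2048))
  t <- (0:4095) / 2048
  tone <- sin(2 * pi * 100 * t)
  f <- bandpass_zero_lag(tone + 5, 2048)
  # DC rejected
  expect_lt(abs(mean(f)), 1e-2)
  # peak cross-correlation with the input tone at lag 0 (zero phase)
  cc <- stats::ccf(f, tone, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_gt(max(cc$acf), 0.99)
  expect_error(bandpass_zero_lag(tone, 500, 20, 400), "Nyquist")
})

test_that("filtering a time-reversed signal equals reversing the filtered signal", {
  set.seed(2)
  x <- rnorm(2048)
  a <- bandpass_zero_lag(rev(x), 2048)
  b <- rev(bandpass_zero_lag(x, 2048))
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("intensity envelope tracks a known slow modulator", {
  fs <- 2048
  expect_equal(intensity_envelope(matrix(0, 2, fs), fs)$values,
               matrix(0, 2, fs))
  # AM carrier with a known 1 Hz modulator
  set.seed(3)
  t <- (0:(3 * fs - 1)) / fs
  modulator <- 1 + 0.8 * sin(2 * pi * 1 * t)
  carrier <- bandpass_zero_lag(rnorm(length(t)), fs)
  env <- intensity_envelope(modulator * carrier, fs)
  expect_true(all(env$values >= 0))
  expect_gt(cor(env$values[1, ], modulator), 0.95)
  # constant input passes through near its own level away from the edges
  e2 <- intensity_envelope(matrix(2, 1, 3 * fs), fs)
  mid <- (fs):(2 * fs)
  expect_equal(mean(e2$values[1, mid]), 2, tolerance = 1e-6)
  expect_error(intensity_envelope(matrix(1, 1, 100), 6, cutoff = 4), "Nyquist")
})

test_that("segmentation finds the supra-threshold window run", {
  # envelope zero except windows 5..9 (0-based) of 20 windows of 10 frames
  v <- matrix(0, 3, 200)
  v[, 51:100] <- 1
  env <- structure(list(values = v, fs = 1000, cutoff = 4),
                   class = "intensity_envelope")
  seg <- segment_activity(env, window_len = 10L)
  expect_equal(seg$start_frame, 50L)
  expect_equal(seg$end_frame, 100L)
  # brute-force oracle over all windows
  S <- sapply(1:20, function(w) sum(rowMeans(v[, ((w - 1) * 10 + 1):(w * 10)])))
  expect_equal(which(S > mean(S)) - 1L, 5:9)
  # constant envelope: S(w) == threshold everywhere, strict > fails
  env_c <- structure(list(values = matrix(1, 3, 200), fs = 1000, cutoff = 4),
                     class = "intensity_envelope")
  expect_error(segment_activity(env_c, 10L), "no activity detected")
  # positive scaling leaves the segment unchanged
  env_s <- env; env_s$values <- env$values * 37.5
  seg_s <- segment_activity(env_s, 10L)
  expect_equal(seg_s$start_frame, seg$start_frame)
  expect_equal(seg_s$end_frame, seg$end_frame)
})

test_that("segment length is a multiple of the window and trailing frames are dropped", {
  set.seed(4)
  v <- matrix(abs(rnorm(1 * 1037)) * 0.01, 1)
  v[, 301:600] <- v[, 301:600] + 5
  env <- structure(list(values = v, fs = 2048, cutoff = 4),
                   class = "intensity_envelope")
  seg <- segment_activity(env, 150L)
  expect_equal((seg$end_frame - seg$start_frame) %% 150L, 0L)
  expect_lte(seg$end_frame, 900L)  # only 6 complete windows exist
  expect_equal(window_duration_ms(150, 2048), 73.2, tolerance = 1e-3)
})

test_that("segments export as a 0-based half-open interval table", {
  segs <- list(activity_segment(150, 450, 150), activity_segment(0, 300, 150))
  path <- tempfile(fileext = ".tsv")
  write_segments(segs, c("t0", "t1"), path)
  tab <- read.delim(path)
  expect_equal(tab$start_frame, c(150, 0))
  expect_equal(tab$end_frame, c(450, 300))
  unlink(path)
})
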