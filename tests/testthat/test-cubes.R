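test_that("image sequences are built from normalized recordings over segments", {
  g <- electrode_grid(8, 16)
  set.seed(1)
  rec <- recording(matrix(runif(128 * 1000), 128, 1000), 1000, g,
                   meta = list(gesture = 2L))
  s <- build_image_sequence(rec)
  expect_equal(dim(s$frames), c(1000, 8, 16))
  expect_equal(s$label, 2L)
  # images match frame_to_image frame by frame (spot checks)
  for (f in c(0, 499, 999))
    expect_equal(s$frames[f + 1, , ], frame_to_image(rec, f))
  # restriction to a segment
  seg <- activity_segment(300, 600, 150)
  s2 <- build_image_sequence(rec, seg)
  expect_equal(dim(s2$frames)[1], 300)
  expect_equal(s2$frames[1, , ], frame_to_image(rec, 300))
  # constant frames give identical images
  rc <- recording(matrix(0.5, 6, 10), 1000, tiny_grid())
  sc <- build_image_sequence(rc, label = 0L)
  expect_true(all(sc$frames == 0.5))
  # un-normalized input is rejected
  bad <- recording(matrix(rnorm(6 * 10), 6, 10) * 3, 1000, tiny_grid())
  expect_error(build_image_sequence(bad), "un-normalized")
})

test_that("cube extraction count follows floor((len - l) / stride) + 1", {
  s <- unit_sequence(len = 1000, h = 2, w = 3)
  expect_equal(dim(extract_cubes(s, 10, 10)$cubes)[4], 100)
  expect_equal(dim(extract_cubes(s, 10, 2)$cubes)[4], 496)
  s10 <- unit_sequence(len = 10, h = 2, w = 3)
  d1 <- extract_cubes(s10, 10, 3)
  expect_equal(dim(d1$cubes)[4], 1)
  expect_equal(d1$cubes[, , , 1], s10$frames)
  expect_error(extract_cubes(s10, 11, 1), "shorter")
  # exhaustive check against a brute-force window enumerator
  for (len in c(7, 12, 20)) for (l in c(1, 3, 5)) for (stride in c(1, 2, 4)) {
    s <- unit_sequence(len = len, h = 2, w = 2, seed = len + l + stride)
    ds <- extract_cubes(s, l, stride)
    starts <- seq(0, len - l, by = stride)
    expect_equal(dim(ds$cubes)[4], length(starts))
    for (i in seq_along(starts))
      expect_equal(ds$cubes[, , , i],
                   s$frames[(starts[i] + 1):(starts[i] + l), , , drop = FALSE][, , , drop = TRUE],
                   ignore_attr = TRUE)
  }
})

test_that("cubes inherit labels and bind across sequences", {
  s0 <- unit_sequence(len = 20, label = 0L, seed = 1)
  s1 <- unit_sequence(len = 30, label = 1L, seed = 2)
  ds <- bind_cubes(list(extract_cubes(s0, 10, 10), extract_cubes(s1, 10, 10)))
  expect_equal(ds$labels, c(0L, 0L, 1L, 1L, 1L))
})

test_that("ms-to-frames conversion floors at the sampling rate", {
  expect_equal(window_frames(150, 2048), 307L)
  expect_equal(window_frames(10, 2048), 20L)
  expect_equal(window_frames(10, 1000), 10L)
  expect_error(window_frames(0, 1000))
})

test_that("trial splits are deterministic partitions", {
  trials <- as.list(letters[1:10])
  hh <- split_trials(trials, "half-half-by-trial")
  expect_equal(length(hh$train), 5)
  expect_equal(length(hh$test), 5)
  expect_equal(unlist(hh$train), letters[c(1, 3, 5, 7, 9)])
  loo <- split_trials(trials, "leave-one-trial-out", k = 3)
  expect_equal(unlist(loo$test), "d")
  expect_equal(length(loo$train), 9)
  # each trial appears in test exactly once over all folds
  seen <- unlist(lapply(0:9, function(k)
    unlist(split_trials(trials, "leave-one-trial-out", k = k)$test)))
  expect_equal(sort(seen), letters[1:10])
  expect_error(split_trials(trials, "leave-one-trial-out", k = 10), "out of range")
})

test_that("cube datasets round-trip through HDF5", {
  ds <- extract_cubes(unit_sequence(len = 25, label = 1L), 10, 5,
                      origin = "train")
  path <- tempfile(fileext = ".h5")
  save_cubes(ds, path)
  back <- load_cubes(path)
  expect_equal(back$cubes, ds$cubes)
  expect_equal(back$labels, ds$labels)
  expect_equal(back$l, ds$l)
  expect_equal(back$stride, ds$stride)
  expect_equal(back$origin, "train")
  unlink(path)
})
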