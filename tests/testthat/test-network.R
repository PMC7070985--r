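test_that("reference 3D convolution matches direct enumeration and shape rules", {
  # all-zero kernel with bias 1 and identity activation: constant-1 output
  x <- array(runif(5 * 5 * 5), c(5, 5, 5))
  k0 <- array(0, c(3, 3, 3, 1, 1))
  out <- conv3d_reference(x, k0, bias = 1)
  expect_true(all(out == 1))
  expect_equal(dim(out), c(3, 3, 3, 1))
  # shape arithmetic: 10 x 8 x 16 input, 3^3 kernel, no padding
  x2 <- array(0, c(10, 8, 16))
  expect_equal(dim(conv3d_reference(x2, k0))[1:3], c(8, 6, 14))
  # independent enumeration oracle on a random case
  set.seed(9)
  x3 <- array(rnorm(5 * 5 * 5), c(5, 5, 5))
  kr <- array(rnorm(27), c(3, 3, 3, 1, 1))
  ref <- conv3d_reference(x3, kr, bias = 0.3)
  pos <- expand.grid(x = 1:3, y = 1:3, z = 1:3)
  for (i in sample(nrow(pos), 5)) {
    p <- pos[i, ]
    acc <- 0.3
    for (dp in 0:2) for (dq in 0:2) for (dr in 0:2)
      acc <- acc + kr[dp + 1, dq + 1, dr + 1, 1, 1] *
        x3[p$x + dp, p$y + dq, p$z + dr]
    expect_equal(ref[p$x, p$y, p$z, 1], acc)
  }
  # ReLU activation applies elementwise
  refr <- conv3d_reference(x3, kr, bias = 0.3, activation = function(v) pmax(v, 0))
  expect_equal(refr, pmax(ref, 0))
  expect_error(conv3d_reference(array(0, c(2, 2, 2)), kr), "larger")
})

test_that("fast convolution layer agrees with the reference across shapes", {
  set.seed(11)
  combos <- expand.grid(l = c(4, 6), h = c(4, 7), w = c(5, 6),
                        ci = c(1, 2), co = c(1, 3))
  expect_gte(nrow(combos), 20)
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    x <- array(rnorm(cb$l * cb$h * cb$w * cb$ci), c(cb$l, cb$h, cb$w, cb$ci))
    k <- array(rnorm(3^3 * cb$ci * cb$co), c(3, 3, 3, cb$ci, cb$co))
    b <- rnorm(cb$co)
    pad <- if (i %% 2 == 0) c(0L, 1L, 1L) else c(0L, 0L, 0L)
    ref <- conv3d_reference(x, k, b, pad = pad)
    x5 <- x; dim(x5) <- c(dim(x), 1L)
    fast <- emg3d:::conv3d_forward_cpp(x5, k, b, pad)
    expect_lt(max(abs(as.vector(ref) - as.vector(fast))), 1e-5)
  }
})

test_that("3D architecture shape propagation follows the paper geometry", {
  spec <- build_3d_cnn(c(10, 8, 16), pool_s = 2, G = 8)
  shapes <- propagate_shapes(spec)
  temporal <- vapply(shapes[vapply(shapes, length, 1L) == 4], `[[`, 1L, 1)
  # temporal trace 10 -> 8 -> 6 -> 3 -> 1 -> 1 across conv/pool layers
  expect_equal(unique(temporal), c(8L, 6L, 3L, 1L))
  spec_csl <- build_3d_cnn(c(20, 7, 24), pool_s = 4, G = 27)
  expect_s3_class(spec_csl, "network_spec")
  expect_error(build_3d_cnn(c(3, 8, 16), pool_s = 2, G = 8), "collapses")
})

test_that("2D ablation spatial traces and l-independence hold", {
  s1 <- build_2d_cnn(c(8, 16), G = 8)
  sh <- propagate_shapes(s1)
  spat <- unique(t(vapply(sh[vapply(sh, length, 1L) == 4],
                          function(x) x[2:3], integer(2))))
  expect_equal(spat, matrix(c(6L, 14L), 1))
  s2 <- build_2d_cnn(c(7, 24), G = 27)
  sh2 <- propagate_shapes(s2)
  spat2 <- unique(t(vapply(sh2[vapply(sh2, length, 1L) == 4],
                           function(x) x[2:3], integer(2))))
  expect_equal(spat2, matrix(c(5L, 22L), 1))
  s3 <- build_2d_cnn(c(3, 3), G = 2)
  sh3 <- propagate_shapes(s3)
  expect_equal(sh3[[1]][2:3], c(1L, 1L))
})

test_that("parameter counting matches hand arithmetic and instantiated tensors", {
  # single conv3d(32, 3x3x3, 1 input map): 32 * (27 + 1) = 896
  spec1 <- new_spec_for_test(list(list(type = "conv", n = 32L,
                                       kernel = c(3L, 3L, 3L), pad = c(0L, 0L, 0L))),
                             c(10L, 8L, 16L), 8L)
  expect_equal(count_parameters(spec1), 896)
  # dense 5376 -> 512
  spec2 <- new_spec_for_test(list(list(type = "flatten"),
                                  list(type = "dense", n = 512L)),
                             c(1L, 84L, 64L), 8L)
  expect_equal(count_parameters(spec2), 5376 * 512 + 512)
  # counts equal the exhaustive enumeration of instantiated tensors
  spec <- build_3d_cnn(c(10, 8, 16), pool_s = 2, G = 8,
                       n_kernels = c(4, 6, 6), fc = c(32, 16))
  params <- emg3d:::init_params(spec)
  for (cv in c("trainable", "with-statistics", "none")) {
    total <- 0
    for (i in seq_along(params)) {
      p <- params[[i]]
      if (is.null(p)) next
      if (spec$layers[[i]]$type == "batchnorm") {
        if (cv == "none") next
        total <- total + length(p$gamma) + length(p$beta)
        if (cv == "with-statistics")
          total <- total + length(p$run_mean) + length(p$run_var)
      } else {
        total <- total + length(p$W) + length(p$b)
      }
    }
    expect_equal(count_parameters(spec, cv), total, info = cv)
  }
})

test_that("learning-rate halving triggers on plateaus only", {
  expect_equal(lr_schedule(seq(1, 0.1, length.out = 20), 0.1), 0.1)
  expect_equal(lr_schedule(c(0.5, rep(0.5, 10)), 0.1), 0.05)
  expect_error(lr_schedule(numeric(0), 0.1), "empty")
  # three consecutive plateaus, applied stepwise with reset: lr0 / 8
  lr <- 0.1
  for (block in 1:3) {
    hist <- c(0.5, rep(0.5, 10))
    lr <- lr_schedule(hist, lr)
  }
  expect_equal(lr, 0.1 / 8)
  # short histories never trigger
  expect_equal(lr_schedule(rep(1, 5), 0.2, patience = 10), 0.2)
})

test_that("network specs round-trip through YAML", {
  spec <- build_3d_cnn(c(10, 8, 16), pool_s = 2, G = 8)
  path <- tempfile(fileext = ".yaml")
  write_network_spec(spec, path)
  back <- read_network_spec(path)
  expect_equal(back$input_shape, spec$input_shape)
  expect_equal(count_parameters(back), count_parameters(spec))
  unlink(path)
})

test_that("binary cross-entropy matches the closed form", {
  y <- c(1, 0, 1)
  p <- c(0.9, 0.2, 0.6)
  expect_equal(binary_cross_entropy(y, p),
               -mean(c(log(0.9), log(0.8), log(0.6))))
})
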