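test_that("per-window fraction correct follows m / nc x 100", {
  expect_equal(eq3_fraction(c(1, 1, 2), 1), 100 * 2 / 3)
  expect_equal(eq3_fraction(c(1, 1, 1, 2), 1), 75)
  expect_equal(eq3_fraction(rep(5, 8), 5), 100)
  expect_error(eq3_fraction(integer(0), 1), "empty")
  # invariant under permutation
  set.seed(1)
  p <- sample(0:2, 20, replace = TRUE)
  expect_equal(eq3_fraction(p, 1), eq3_fraction(sample(p), 1))
})

test_that("majority vote picks the mode, ties resolved to the most recent", {
  expect_equal(majority_vote(c(2, 2, 3)), 2)
  expect_equal(majority_vote(c(1)), 1)
  expect_equal(majority_vote(c(1, 2, 1, 2)), 2)
  expect_error(majority_vote(integer(0)), "empty")
  # exhaustive check of the tie rule over all length-4 binary sequences
  for (i in 0:15) {
    seqb <- as.integer(intToBits(i))[1:4]
    counts <- table(factor(seqb, levels = 0:1))
    expected <- if (counts[1] > counts[2]) 0L else if (counts[2] > counts[1]) 1L
                else seqb[4]  # tie: whichever label occurs last occurs most recently
    # on a 2-2 tie both labels occur in the last two positions; the most
    # recent occurrence overall is the final element
    expect_equal(majority_vote(seqb), expected, info = paste(seqb, collapse = ""))
  }
})

test_that("voted evaluation reduces to per-cube accuracy at nc = 1 and to the binomial tail otherwise", {
  set.seed(42)
  # synthetic i.i.d. per-cube predictions, binary task, error rate 0.3
  n_windows <- 2000
  nc <- 5
  preds <- lapply(seq_len(n_windows), function(i)
    ifelse(runif(nc) < 0.3, 1L, 0L))  # truth is 0
  truths <- rep(0L, n_windows)
  r <- emg3d:::voted_from_predictions(preds, truths, nc, 2L)
  voted_err <- 1 - r$accuracy / 100
  expected_err <- sum(dbinom(3:5, 5, 0.3))
  mc_sd <- sqrt(expected_err * (1 - expected_err) / n_windows)
  expect_lt(abs(voted_err - expected_err), 4 * mc_sd)
  # nc = 1: voted accuracy equals per-cube accuracy exactly
  flat <- unlist(preds)
  r1 <- emg3d:::voted_from_predictions(list(flat), 0L, 1L, 2L)
  expect_equal(r1$accuracy, 100 * mean(flat == 0L))
  # confusion counts sum to the number of decisions
  expect_equal(sum(r$confusion), r$n_decisions)
  expect_equal(r$n_decisions, n_windows)
})

test_that("degenerate classifiers give 0% and 100% voted accuracy", {
  perfect <- lapply(1:4, function(i) rep(1L, 12))
  r <- emg3d:::voted_from_predictions(perfect, rep(1L, 4), 3L, 3L)
  expect_equal(r$accuracy, 100)
  wrong <- lapply(1:4, function(i) rep(0L, 12))
  r0 <- emg3d:::voted_from_predictions(wrong, rep(1L, 4), 3L, 3L)
  expect_equal(r0$accuracy, 0)
  # trailing cubes not filling a window are dropped
  r2 <- emg3d:::voted_from_predictions(list(rep(1L, 7)), 1L, 3L, 2L)
  expect_equal(r2$n_decisions, 2)
})

test_that("whole-trial voting and window sweeps work on a trained model", {
  ds <- separable_cubes(n = 80)
  spec <- tiny_spec(G = 2)
  model <- fit_network(spec, ds, training_config(max_epochs = 10, seed = 1))
  # build labeled sequences whose cubes resemble the training classes
  mk_seq <- function(label, seed) {
    set.seed(seed)
    fr <- array(runif(60 * 5 * 7) * 0.1, c(60, 5, 7))
    if (label == 1) fr[, 1:2, 1:2] <- fr[, 1:2, 1:2] + 0.5
    image_sequence(fr, fs = 1000, label = label)
  }
  seqs <- list(mk_seq(0L, 1), mk_seq(1L, 2), mk_seq(0L, 3), mk_seq(1L, 4))
  ev <- evaluate_voted(model, seqs, l_cube = 10, voting_ms = 30)
  expect_gte(ev$accuracy, 75)
  expect_equal(sum(ev$confusion), ev$n_decisions)
  expect_equal(ev$nc, 3)
  # entire-trial vote agrees with the dominant per-cube prediction
  v <- vote_entire_trial(model, seqs[[2]], l_cube = 10)
  expect_equal(v, 1L)
  # sweep: the nc = 1 point equals raw per-cube accuracy
  sw <- accuracy_vs_window_sweep(model, seqs, 10, c(10, 30, 60))
  preds <- emg3d:::cube_predictions(model, seqs, 10)
  acc_cube <- 100 * mean(unlist(preds) ==
                           rep(vapply(seqs, `[[`, integer(1), "label"),
                               vapply(preds, length, integer(1))))
  expect_equal(sw$accuracy_pct[sw$window_ms == 10], acc_cube)
  expect_equal(sw$nc, c(1, 3, 6))
  # a window longer than the real-time bound warns
  long_seq <- list(mk_seq(0L, 9))
  long_seq[[1]]$frames <- long_seq[[1]]$frames[rep(1:60, 7), , ]
  expect_warning(evaluate_voted(model, long_seq, 10, 400), "300 ms")
})

test_that("confusion matrices export with gesture-index headers", {
  cm <- confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1), 2)
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 2L), 2,
                                   dimnames = list(true = 0:1, pred = 0:1)))
  pct <- confusion_percent(cm)
  expect_equal(rowSums(pct), c(`0` = 100, `1` = 100))
  path <- tempfile(fileext = ".csv")
  write_confusion(cm, path)
  tab <- read.csv(path)
  expect_equal(tab$gesture, c(0, 1))
  unlink(path)
})
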