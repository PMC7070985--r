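#' Fraction of correct recognitions in a voting window
#'
#' The per-window recognition accuracy `P = m / nc * 100%`, where `m` of the
#' `nc` consecutive recognition results equal the target gesture.
#'
#' @param predictions Nonempty vector of predicted labels.
#' @param target True gesture label.
#' @return Percentage in `[0, 100]`.
#' @examples eq3_fraction(c(1, 1, 2), 1) # 66.67
#' @export
eq3_fraction <- function(predictions, target) {
  if (length(predictions) == 0) stop("empty prediction sequence")
  100 * mean(predictions == target)
}

#' Majority vote over consecutive predictions
#'
#' Returns the modal label of the sequence. Ties are broken in favor of the
#' tied label whose most recent occurrence is latest, preferring the newest
#' evidence as an online controller would.
#'
#' @param predictions Nonempty vector of predicted labels.
#' @return The winning label.
#' @examples
#' majority_vote(c(2, 2, 3))    # 2
#' majority_vote(c(1, 2, 1, 2)) # 2 (tie; 2 occurred most recently)
#' @export
majority_vote <- function(predictions) {
  n <- length(predictions)
  if (n == 0) stop("empty prediction sequence")
  tab <- table(predictions)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1) {
    win <- top
  } else {
    last_seen <- vapply(top, function(lb) max(which(predictions == lb)), numeric(1))
    win <- top[which.max(last_seen)]
  }
  # restore the original type
  if (is.numeric(predictions)) as.numeric(win) else win
}

#' Accumulated confusion matrix
#'
#' `G x G` integer counts with rows = true gesture, columns = predicted
#' gesture (0-based indices on the dimnames). Row-normalized percentages are
#' derived on demand via [confusion_percent()].
#'
#' @param true,pred 0-based label vectors.
#' @param G Number of classes.
#' @return An object of class `confusion_matrix` (an integer matrix).
#' @export
confusion_matrix <- function(true, pred, G) {
  counts <- matrix(0L, G, G, dimnames = list(true = 0:(G - 1), pred = 0:(G - 1)))
  for (i in seq_along(true))
    counts[true[i] + 1L, pred[i] + 1L] <- counts[true[i] + 1L, pred[i] + 1L] + 1L
  structure(counts, class = c("confusion_matrix", "matrix", "array"))
}

#' @rdname confusion_matrix
#' @param cm A `confusion_matrix`.
#' @export
confusion_percent <- function(cm) {
  rs <- rowSums(cm)
  rs[rs == 0] <- 1
  100 * unclass(cm) / rs
}

#' Write a confusion matrix as CSV with gesture-index headers
#' @param cm A `confusion_matrix`.
#' @param path Output path.
#' @export
write_confusion <- function(cm, path) {
  df <- as.data.frame(unclass(cm))
  utils::write.csv(cbind(gesture = rownames(cm), df), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# Per-cube predictions for each test sequence: non-overlapping cubes
# (stride = l_cube), one label vector per sequence.
cube_predictions <- function(model, sequences, l_cube) {
  lapply(sequences, function(s) {
    ds <- extract_cubes(s, l_cube, stride = l_cube, origin = "test")
    predict(model, ds)$labels
  })
}

voted_from_predictions <- function(preds, truths, nc, G) {
  decisions <- integer(0); dec_true <- integer(0); eq3 <- numeric(0)
  for (i in seq_along(preds)) {
    p <- preds[[i]]
    nwin <- length(p) %/% nc
    if (nwin == 0) next
    for (wdx in seq_len(nwin)) {
      seg <- p[((wdx - 1L) * nc + 1L):(wdx * nc)]
      decisions <- c(decisions, majority_vote(seg))
      dec_true <- c(dec_true, truths[i])
      eq3 <- c(eq3, eq3_fraction(seg, truths[i]))
    }
  }
  if (length(decisions) == 0) stop("no complete voting window in any sequence")
  list(accuracy = 100 * mean(decisions == dec_true),
       confusion = confusion_matrix(dec_true, decisions, G),
       eq3_mean = mean(eq3), n_decisions = length(decisions))
}

#' Majority-voted evaluation over test sequences
#'
#' Splits each test sequence into non-overlapping cubes of `l_cube` frames,
#' predicts each cube, and groups `nc = floor(voting_ms / t_cube)`
#' consecutive predictions into non-overlapping voting windows, where
#' `t_cube = 1000 * l_cube / fs` ms is the cube duration. Each window issues
#' one majority-vote decision; the headline accuracy is the percentage of
#' windows whose decision equals the true gesture (the per-window
#' fraction-correct is also reported as `eq3_mean`). Windows never span trial
#' boundaries and trailing cubes not filling a window are dropped. A voting
#' window longer than the 300 ms real-time bound triggers a warning, not an
#' error.
#'
#' @param model A trained `emg_model`.
#' @param sequences List of labeled [image_sequence()]s (test trials).
#' @param l_cube Frames per cube.
#' @param voting_ms Voting-window length in ms (must cover at least one cube).
#' @return List with `accuracy` (percent), `confusion`
#'   ([confusion_matrix()]), `eq3_mean`, `n_decisions`, `nc`.
#' @export
evaluate_voted <- function(model, sequences, l_cube, voting_ms) {
  stopifnot(length(sequences) >= 1)
  fs <- sequences[[1]]$fs
  t_cube <- 1000 * l_cube / fs
  nc <- floor(voting_ms / t_cube)
  if (nc < 1) stop("voting window shorter than one cube duration")
  if (nc * t_cube > 300)
    warning(sprintf("voting window %.0f ms exceeds the 300 ms real-time bound",
                    nc * t_cube))
  preds <- cube_predictions(model, sequences, l_cube)
  truths <- vapply(sequences, `[[`, integer(1), "label")
  out <- voted_from_predictions(preds, truths, nc, model$spec$G)
  out$nc <- nc
  out
}

#' Majority vote over an entire trial
#'
#' A single gesture decision per trial from all of its non-overlapping cube
#' predictions.
#'
#' @param model A trained `emg_model`.
#' @param sequence A labeled [image_sequence()].
#' @param l_cube Frames per cube.
#' @return The voted 0-based label.
#' @export
vote_entire_trial <- function(model, sequence, l_cube) {
  preds <- cube_predictions(model, list(sequence), l_cube)[[1]]
  majority_vote(preds)
}

#' Accuracy as a function of voting-window length
#'
#' Evaluates [evaluate_voted()] over a grid of voting-window lengths, reusing
#' the per-cube predictions, and returns a two-column table suitable for
#' plotting accuracy-vs-window curves.
#'
#' @param model A trained `emg_model`.
#' @param sequences List of labeled [image_sequence()]s.
#' @param l_cube Frames per cube.
#' @param window_grid Ascending vector of voting-window lengths in ms.
#' @return `data.frame` with columns `window_ms`, `nc`, `accuracy_pct`.
#' @export
accuracy_vs_window_sweep <- function(model, sequences, l_cube, window_grid) {
  stopifnot(!is.unsorted(window_grid))
  fs <- sequences[[1]]$fs
  t_cube <- 1000 * l_cube / fs
  preds <- cube_predictions(model, sequences, l_cube)
  truths <- vapply(sequences, `[[`, integer(1), "label")
  rows <- lapply(window_grid, function(ms) {
    nc <- floor(ms / t_cube)
    if (nc < 1) return(NULL)
    r <- voted_from_predictions(preds, truths, nc, model$spec$G)
    data.frame(window_ms = ms, nc = nc, accuracy_pct = r$accuracy)
  })
  do.call(rbind, rows)
}
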