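#' Sequence of instantaneous sEMG images
#'
#' One grayscale image per time frame, values in `[0, 1]`, stored as an
#' `l_total x h x w` array.
#'
#' @param frames `l_total x h x w` array in `[0, 1]`.
#' @param fs Sampling rate in Hz.
#' @param label 0-based gesture index (or `NA` if unlabeled).
#' @param meta Provenance list.
#' @return An object of class `image_sequence`.
#' @export
image_sequence <- function(frames, fs, label = NA_integer_, meta = list()) {
  stopifnot(length(dim(frames)) == 3)
  rng <- range(frames)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("un-normalized input: image values must lie in [0, 1]")
  structure(list(frames = frames, fs = fs,
                 label = if (is.na(label)) NA_integer_ else as.integer(label),
                 meta = as.list(meta)),
            class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_sequence> %d frames of %d x %d @ %g Hz, label %s\n",
              d[1], d[2], d[3], x$fs,
              if (is.na(x$label)) "NA" else x$label))
  invisible(x)
}

#' @export
length.image_sequence <- function(x) dim(x$frames)[1]

#' Build the sEMG image sequence of a trial
#'
#' Converts a `[0, 1]`-normalized recording into one instantaneous image per
#' frame, restricted to an activity segment if one is given. Each image is
#' formed via the grid's channel map exactly as [frame_to_image()].
#'
#' @param rec A normalized [recording()] (all values in `[0, 1]`).
#' @param segment Optional [activity_segment()]; `NULL` uses the whole trial.
#' @param label 0-based gesture index attached to the sequence; defaults to
#'   `rec$meta$gesture` when present.
#' @return An [image_sequence()].
#' @export
build_image_sequence <- function(rec, segment = NULL, label = NULL) {
  stopifnot(inherits(rec, "emg_recording"))
  rng <- range(rec$signal)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("un-normalized input: recording values must lie in [0, 1]")
  idx <- if (is.null(segment)) seq_len(n_frames(rec)) else {
    if (segment$end_frame > n_frames(rec)) stop("segment exceeds recording length")
    (segment$start_frame + 1L):segment$end_frame
  }
  g <- rec$grid
  cm <- g$channel_map
  # channel occupying each pixel, pixels enumerated row-major (col fastest)
  chan_at_pixel <- integer(g$rows * g$cols)
  chan_at_pixel[cm[, 1] * g$cols + cm[, 2] + 1L] <- seq_len(nrow(cm))
  M <- rec$signal[chan_at_pixel, idx, drop = FALSE]     # pixels x frames
  A <- array(t(M), dim = c(length(idx), g$cols, g$rows))
  frames <- aperm(A, c(1, 3, 2))
  if (is.null(label)) label <- if (!is.null(rec$meta$gesture)) rec$meta$gesture else NA
  image_sequence(frames, rec$fs, label = label, meta = rec$meta)
}

#' Labeled spatiotemporal cube dataset
#'
#' Classifier-ready stacks of `l` consecutive sEMG images. Cubes are stored as
#' an `l x h x w x n` array (one implicit grayscale channel); labels are
#' 0-based gesture indices.
#'
#' @param cubes `l x h x w x n` array.
#' @param labels Integer vector of length `n`.
#' @param l Frames per cube.
#' @param stride Extraction stride in frames.
#' @param fs Sampling rate in Hz.
#' @param origin Free-text tag (e.g. `"train"` or `"test"`).
#' @return An object of class `cube_dataset`.
#' @export
cube_dataset <- function(cubes, labels, l, stride, fs, origin = "unspecified") {
  stopifnot(length(dim(cubes)) == 4, dim(cubes)[4] == length(labels),
            dim(cubes)[1] == l)
  structure(list(cubes = cubes, labels = as.integer(labels),
                 l = as.integer(l), stride = as.integer(stride),
                 fs = fs, origin = origin),
            class = "cube_dataset")
}

#' @export
print.cube_dataset <- function(x, ...) {
  d <- dim(x$cubes)
  cat(sprintf("<cube_dataset> %d cubes of %d x %d x %d (stride %d, %s), %d classes\n",
              d[4], d[1], d[2], d[3], x$stride, x$origin,
              length(unique(x$labels))))
  invisible(x)
}

#' Extract sliding-window cubes from an image sequence
#'
#' Cuts an image sequence into cubes of `l` consecutive frames starting at
#' frame 0 and advancing by `stride`; the last window must lie fully inside
#' the sequence, so the cube count is `floor((len - l) / stride) + 1`. A
#' stride of 2 on the training set implements the overlap data-augmentation
#' strategy; test-time extraction uses `stride = l` (non-overlapping).
#'
#' @param seq An [image_sequence()].
#' @param l Frames per cube (`>= 1`).
#' @param stride Step between cube starts in frames (`>= 1`).
#' @param origin Tag stored on the resulting dataset.
#' @return A [cube_dataset()]; every cube inherits the sequence's label.
#' @export
extract_cubes <- function(seq, l, stride, origin = "unspecified") {
  stopifnot(inherits(seq, "image_sequence"), l >= 1, stride >= 1)
  len <- dim(seq$frames)[1]
  if (len < l) stop("sequence shorter than one cube (", len, " < ", l, ")")
  n <- (len - l) %/% stride + 1L
  d <- dim(seq$frames)
  cubes <- array(0, dim = c(l, d[2], d[3], n))
  for (i in seq_len(n)) {
    s <- (i - 1L) * stride
    cubes[, , , i] <- seq$frames[(s + 1L):(s + l), , , drop = FALSE]
  }
  cube_dataset(cubes, rep(seq$label, n), l, stride, seq$fs, origin)
}

#' Bind several cube datasets
#' @param ... `cube_dataset`s with identical cube shape and fs.
#' @return A single [cube_dataset()].
#' @export
bind_cubes <- function(...) {
  ds <- list(...)
  if (length(ds) == 1 && is.list(ds[[1]]) && !inherits(ds[[1]], "cube_dataset"))
    ds <- ds[[1]]
  stopifnot(length(ds) >= 1)
  d1 <- dim(ds[[1]]$cubes)[1:3]
  for (x in ds) stopifnot(all(dim(x$cubes)[1:3] == d1))
  cubes <- array(unlist(lapply(ds, function(x) x$cubes)),
                 dim = c(d1, sum(vapply(ds, function(x) dim(x$cubes)[4], numeric(1)))))
  cube_dataset(cubes, unlist(lapply(ds, `[[`, "labels")),
               ds[[1]]$l, ds[[1]]$stride, ds[[1]]$fs, ds[[1]]$origin)
}

#' Convert a window duration from milliseconds to frames
#'
#' `floor(duration_ms * fs / 1000)`; at 2048 Hz, 150 ms spans 307 frames and
#' 10 ms spans 20 frames. At 1000 Hz milliseconds and frames coincide.
#'
#' @param duration_ms Positive duration in ms.
#' @param fs Sampling rate in Hz.
#' @return Integer number of frames.
#' @export
window_frames <- function(duration_ms, fs) {
  stopifnot(duration_ms > 0)
  as.integer(floor(duration_ms * fs / 1000))
}

#' Split labeled trials into training and testing sets
#'
#' Deterministic partition of a list of trials. `"half-half-by-trial"`
#' assigns even-indexed trials (0-based: trials 0, 2, 4, ...) to training and
#' odd-indexed trials to testing, the CapgMyo-style protocol;
#' `"leave-one-trial-out"` puts trial `k` (0-based) in the test set and the
#' rest in training, the CSL-style protocol.
#'
#' @param trials List (e.g. of [image_sequence()]s or recordings).
#' @param scheme `"half-half-by-trial"` or `"leave-one-trial-out"`.
#' @param k Held-out 0-based trial index for leave-one-trial-out.
#' @return List with elements `train` and `test`.
#' @export
split_trials <- function(trials, scheme = c("half-half-by-trial", "leave-one-trial-out"),
                         k = NULL) {
  scheme <- match.arg(scheme)
  n <- length(trials)
  if (scheme == "half-half-by-trial") {
    idx0 <- seq_len(n) - 1L
    list(train = trials[idx0 %% 2L == 0L], test = trials[idx0 %% 2L == 1L])
  } else {
    if (is.null(k) || k < 0 || k >= n)
      stop("k out of range for leave-one-trial-out: need 0 <= k < ", n)
    list(train = trials[-(k + 1L)], test = trials[k + 1L])
  }
}

#' Save / load a cube dataset as HDF5
#'
#' Datasets `cubes` (l x h x w x n) and `labels`, plus scalar datasets
#' `l`, `stride`, `fs`, `origin`.
#'
#' @param ds A [cube_dataset()].
#' @param path HDF5 file path.
#' @return `path` (save) or a `cube_dataset` (load).
#' @export
save_cubes <- function(ds, path) {
  stopifnot(inherits(ds, "cube_dataset"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(ds$cubes, path, "cubes")
  rhdf5::h5write(ds$labels, path, "labels")
  rhdf5::h5write(ds$l, path, "l")
  rhdf5::h5write(ds$stride, path, "stride")
  rhdf5::h5write(ds$fs, path, "fs")
  rhdf5::h5write(ds$origin, path, "origin")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname save_cubes
#' @export
load_cubes <- function(path) {
  cubes <- rhdf5::h5read(path, "cubes")
  ds <- cube_dataset(cubes,
                     as.integer(rhdf5::h5read(path, "labels")),
                     as.integer(rhdf5::h5read(path, "l")),
                     as.integer(rhdf5::h5read(path, "stride")),
                     as.numeric(rhdf5::h5read(path, "fs")),
                     as.character(rhdf5::h5read(path, "origin")))
  rhdf5::h5closeAll()
  ds
}
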