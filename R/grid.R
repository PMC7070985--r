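#' Electrode grid geometry
#'
#' Describes the 2D arrangement of an HD-sEMG electrode grid and the mapping
#' from channel indices to pixel positions. A CapgMyo-style monopolar grid is
#' 8 rows by 16 columns (128 channels); a CSL-style bipolar montage yields
#' 7 x 24 usable channels.
#'
#' @param rows,cols Positive integers, grid height `h` and width `w`.
#' @param channel_map Integer matrix with `rows * cols` rows and two columns
#'   (`row`, `col`), 0-based: row `k` gives the pixel of channel `k - 1`.
#'   Defaults to row-major order (channel 0 at pixel (0, 0), channel 1 at
#'   (0, 1), ...). Must be a bijection onto the grid.
#' @param layout_name Free-text label for the layout.
#' @return An object of class `electrode_grid`.
#' @examples
#' g <- electrode_grid(8, 16)
#' g$rows * g$cols
#' @export
electrode_grid <- function(rows, cols, channel_map = NULL,
                           layout_name = sprintf("%dx%d", rows, cols)) {
  stopifnot(is.numeric(rows), is.numeric(cols), rows >= 1, cols >= 1,
            rows == round(rows), cols == round(cols))
  rows <- as.integer(rows); cols <- as.integer(cols)
  n <- rows * cols
  if (is.null(channel_map)) {
    # row-major default: channel k -> (k %/% cols, k %% cols)
    k <- 0:(n - 1L)
    channel_map <- cbind(row = k %/% cols, col = k %% cols)
  }
  channel_map <- as.matrix(channel_map)
  if (nrow(channel_map) != n || ncol(channel_map) != 2)
    stop("channel_map must have ", n, " rows and 2 columns")
  storage.mode(channel_map) <- "integer"
  dimnames(channel_map) <- list(NULL, c("row", "col"))
  if (any(channel_map[, 1] < 0L) || any(channel_map[, 1] >= rows) ||
      any(channel_map[, 2] < 0L) || any(channel_map[, 2] >= cols))
    stop("channel_map entries out of grid range")
  lin <- channel_map[, 1] * cols + channel_map[, 2]
  if (anyDuplicated(lin))
    stop("channel_map is not a bijection: some pixel claimed more than once")
  structure(list(rows = rows, cols = cols, channel_map = channel_map,
                 layout_name = layout_name),
            class = "electrode_grid")
}

#' @export
print.electrode_grid <- function(x, ...) {
  cat(sprintf("<electrode_grid> %s: %d x %d (%d channels)\n",
              x$layout_name, x$rows, x$cols, x$rows * x$cols))
  invisible(x)
}

#' HD-sEMG recording
#'
#' A multi-channel surface EMG recording tied to an electrode grid. The signal
#' is stored channels x frames; frame and channel indices are 0-based and time
#' intervals are half-open `[start, end)` throughout the package.
#'
#' @param signal Numeric matrix, channels x frames.
#' @param fs Sampling rate in Hz.
#' @param grid An [electrode_grid()]; its channel count must equal `nrow(signal)`.
#' @param meta Named list of provenance metadata (subject, session, trial,
#'   gesture label, ...). Free-form.
#' @return An object of class `emg_recording`.
#' @export
recording <- function(signal, fs, grid, meta = list()) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (!inherits(grid, "electrode_grid")) stop("grid must be an electrode_grid")
  if (nrow(signal) != grid$rows * grid$cols)
    stop(sprintf("channel/grid mismatch: %d channels but grid %d x %d = %d",
                 nrow(signal), grid$rows, grid$cols, grid$rows * grid$cols))
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be a positive scalar")
  if (ncol(signal) < 1) stop("recording must contain at least one frame")
  structure(list(signal = signal, fs = as.numeric(fs), grid = grid,
                 meta = as.list(meta)),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels x %d frames @ %g Hz (grid %s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, x$grid$layout_name))
  if (!is.null(x$meta$gesture)) cat("  gesture:", x$meta$gesture, "\n")
  invisible(x)
}

#' Number of frames in a recording
#' @param rec An `emg_recording`.
#' @export
n_frames <- function(rec) ncol(rec$signal)

#' Form the instantaneous sEMG image of one frame
#'
#' Arranges the instantaneous channel values of a single time frame as an
#' `h x w` grayscale image according to the grid's channel map: pixel
#' `(r, c)` holds the sample of the channel mapped there.
#'
#' @param rec An [recording()].
#' @param frame_index 0-based frame index, `0 <= frame_index < n_frames(rec)`.
#' @return Numeric `h x w` matrix.
#' @examples
#' g <- electrode_grid(2, 3)
#' r <- recording(matrix(0:5, nrow = 6, ncol = 1), fs = 1000, grid = g)
#' frame_to_image(r, 0)
#' @export
frame_to_image <- function(rec, frame_index) {
  stopifnot(inherits(rec, "emg_recording"))
  if (!is.numeric(frame_index) || length(frame_index) != 1 ||
      frame_index != round(frame_index))
    stop("frame_index must be a single integer")
  if (frame_index < 0 || frame_index >= n_frames(rec))
    stop(sprintf("frame_index %d out of range [0, %d)", frame_index, n_frames(rec)))
  vals <- rec$signal[, frame_index + 1L]
  img <- matrix(NA_real_, rec$grid$rows, rec$grid$cols)
  cm <- rec$grid$channel_map
  img[cbind(cm[, 1] + 1L, cm[, 2] + 1L)] <- vals
  img
}

#' Recover a channel vector from an sEMG image
#'
#' Inverse of [frame_to_image()]: reads the image back into channel order
#' through the grid's channel map.
#'
#' @param img `h x w` numeric matrix.
#' @param grid An [electrode_grid()].
#' @return Numeric vector of length `rows * cols` in channel order.
#' @export
image_to_channels <- function(img, grid) {
  stopifnot(inherits(grid, "electrode_grid"))
  if (!all(dim(img) == c(grid$rows, grid$cols))) stop("image/grid shape mismatch")
  cm <- grid$channel_map
  img[cbind(cm[, 1] + 1L, cm[, 2] + 1L)]
}
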