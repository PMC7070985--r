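#' Linear normalization to the unit interval
#'
#' Affine map `x -> (x - lo) / (hi - lo)` with values outside `[lo, hi]`
#' clipped to `[0, 1]`. Pre-segmented CapgMyo-style data in `[-1, 1]` needs
#' only this step before image formation.
#'
#' @param signal Numeric matrix (or vector).
#' @param source_range Length-2 numeric `(lo, hi)`, `hi > lo`. Defaults to the
#'   observed range of `signal`.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
normalize_unit_interval <- function(signal, source_range = range(signal)) {
  lo <- source_range[1]; hi <- source_range[2]
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
    stop("degenerate source_range: need hi > lo")
  out <- (signal - lo) / (hi - lo)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

# Exact zero-phase filtering: the squared magnitude response |H(w)|^2 of the
# IIR prototype (what a forward-backward pass realizes, with its phase
# cancelled exactly) is applied in the frequency domain on an even (mirrored)
# extension of the signal. The even extension supplies symmetric boundary
# handling, and because |H|^2 is real the operation commutes exactly with
# time reversal.
zero_phase_gain <- function(b, a, M) {
  w <- 2 * pi * (0:(M - 1)) / M
  ejw <- exp(-1i * outer(w, 0:(max(length(b), length(a)) - 1)))
  num <- ejw[, seq_along(b), drop = FALSE] %*% b
  den <- ejw[, seq_along(a), drop = FALSE] %*% a
  Mod(num / den)^2
}

# filter a channels x frames matrix (rows are channels) with |H|^2
filt_zero_phase <- function(b, a, x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  M <- 2L * n
  H2 <- zero_phase_gain(b, a, M)
  ext <- cbind(x, x[, n:1, drop = FALSE])
  out <- t(apply(ext, 1, function(ch)
    Re(stats::fft(stats::fft(ch) * H2, inverse = TRUE)) / M))[, seq_len(n),
                                                             drop = FALSE]
  if (vec) out <- drop(out)
  out
}

#' Zero-lag Butterworth band-pass filtering
#'
#' Per-channel forward-backward (zero-phase) Butterworth band-pass filtering,
#' the conditioning step for raw HD-sEMG before intensity extraction. The
#' default 20-400 Hz band covers the surface-EMG signal band while rejecting
#' motion artifact and baseline drift. The zero-phase pass applies the
#' Butterworth squared-magnitude response exactly (the gain a
#' forward-backward filter realizes, with its phase cancelled identically),
#' using an even signal extension for boundary handling, so burst timing is
#' preserved and filtering commutes exactly with time reversal.
#'
#' @param signal Channels x frames numeric matrix (a plain vector is treated
#'   as a single channel).
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz, `0 < low < high < fs / 2`.
#' @param order Butterworth prototype order (the band-pass filter has
#'   `2 * order` poles, the MATLAB/scipy convention).
#' @return Filtered matrix of the same shape.
#' @export
bandpass_zero_lag <- function(signal, fs, low = 20, high = 400, order = 4) {
  if (low <= 0 || high <= low) stop("need 0 < low < high")
  if (high >= fs / 2) stop("high band edge must be below the Nyquist frequency fs/2")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  filt_zero_phase(bf$b, bf$a, signal)
}

#' Rectified intensity envelope
#'
#' Full-wave rectification followed by a zero-lag low-pass Butterworth filter
#' (default 4 Hz cutoff), yielding a smooth per-channel time series tracking
#' muscle activation level. Tiny negative excursions from filter ringing are
#' clamped to zero.
#'
#' @param signal Channels x frames matrix, already band-pass conditioned.
#' @param fs Sampling rate in Hz.
#' @param cutoff Low-pass cutoff in Hz; must be below Nyquist.
#' @param order Butterworth order of the smoothing filter.
#' @return An object of class `intensity_envelope` with fields `values`
#'   (nonnegative channels x frames matrix), `fs`, `cutoff`.
#' @export
intensity_envelope <- function(signal, fs, cutoff = 4, order = 4) {
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency fs/2")
  if (is.null(dim(signal))) signal <- matrix(signal, nrow = 1)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  env <- filt_zero_phase(bf$b, bf$a, abs(signal))
  env[env < 0] <- 0
  structure(list(values = env, fs = fs, cutoff = cutoff),
            class = "intensity_envelope")
}

#' @export
print.intensity_envelope <- function(x, ...) {
  cat(sprintf("<intensity_envelope> %d channels x %d frames @ %g Hz (cutoff %g Hz)\n",
              nrow(x$values), ncol(x$values), x$fs, x$cutoff))
  invisible(x)
}

#' Muscle-activity segment
#'
#' Frame interval of detected activity, half-open `[start_frame, end_frame)`
#' with 0-based frames; its length is always a positive multiple of the
#' detection window.
#'
#' @param start_frame,end_frame Integers, half-open interval bounds.
#' @param window_len Detection window length in frames.
#' @return An object of class `activity_segment`.
#' @export
activity_segment <- function(start_frame, end_frame, window_len) {
  len <- end_frame - start_frame
  if (len <= 0 || len %% window_len != 0)
    stop("segment length must be a positive multiple of window_len")
  structure(list(start_frame = as.integer(start_frame),
                 end_frame = as.integer(end_frame),
                 window_len = as.integer(window_len)),
            class = "activity_segment")
}

#' @export
print.activity_segment <- function(x, ...) {
  cat(sprintf("<activity_segment> [%d, %d) = %d windows of %d frames\n",
              x$start_frame, x$end_frame,
              (x$end_frame - x$start_frame) %/% x$window_len, x$window_len))
  invisible(x)
}

#' Threshold-based activity segmentation
#'
#' Detects the muscle-activity interval of a trial from its intensity
#' envelope. The envelope is cut into non-overlapping windows of `window_len`
#' frames (a trailing partial window is discarded). For window `w` and
#' channel `c` the mean intensity `a(w, c)` is computed; the per-window score
#' is `S(w) = sum_c a(w, c)` and the threshold is the mean of `S` over all
#' windows. Windows with `S(w)` strictly above the threshold are active, and
#' the longest contiguous run of active windows is returned as a frame
#' interval (a single dominant burst per trial is assumed). At 2048 Hz the
#' default 150-sample window spans 73.2 ms.
#'
#' @param env An [intensity_envelope()].
#' @param window_len Detection window length in frames (default 150).
#' @return An [activity_segment()].
#' @export
segment_activity <- function(env, window_len = 150L) {
  stopifnot(inherits(env, "intensity_envelope"))
  v <- env$values
  frames <- ncol(v)
  window_len <- as.integer(window_len)
  if (frames < window_len) stop("fewer frames than one window")
  nwin <- frames %/% window_len
  arr <- array(v[, seq_len(nwin * window_len), drop = FALSE],
               dim = c(nrow(v), window_len, nwin))
  S <- apply(arr, 3, sum) / window_len  # sum over channels of per-window means
  thr <- mean(S)
  active <- S > thr
  if (!any(active)) stop("no activity detected")
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  activity_segment((starts[best] - 1L) * window_len, ends[best] * window_len,
                   window_len)
}

#' Duration of a window in milliseconds
#' @param window_len Window length in frames.
#' @param fs Sampling rate in Hz.
#' @return Duration in ms.
#' @examples window_duration_ms(150, 2048) # 73.2 ms
#' @export
window_duration_ms <- function(window_len, fs) 1000 * window_len / fs

#' Write activity segments as an interval table
#'
#' Tab-separated table with columns `trial_id`, `start_frame`, `end_frame`
#' (0-based, half-open).
#'
#' @param segments List of [activity_segment()]s.
#' @param trial_ids Character or integer vector of trial identifiers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, trial_ids, path) {
  stopifnot(length(segments) == length(trial_ids))
  df <- data.frame(trial_id = trial_ids,
                   start_frame = vapply(segments, `[[`, integer(1), "start_frame"),
                   end_frame = vapply(segments, `[[`, integer(1), "end_frame"))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
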