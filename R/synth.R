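#' Synthetic HD-sEMG generator configuration
#'
#' Parameters of the synthetic electrode-grid simulator. Each trial follows a
#' rest-activity-rest structure: within `[onset, offset]` (fractions of the
#' trial) a smooth amplitude envelope gates a per-channel band-limited noise
#' carrier weighted by the gesture's spatial activation map; outside it only
#' baseline noise remains. Defaults emulate a CapgMyo-style 8 x 16 monopolar
#' grid at 1000 Hz with 3-second trials, a 20-400 Hz carrier band and 10
#' trials per gesture; a CSL-style configuration is
#' `synth_config(G = 27, grid = electrode_grid(7, 24), fs = 2048)`.
#'
#' @param G Number of gestures (>= 2).
#' @param grid An [electrode_grid()].
#' @param fs Sampling rate in Hz.
#' @param trial_s Trial duration in seconds.
#' @param activity_fraction `(onset, offset)` as fractions of the trial,
#'   `0 <= onset < offset <= 1`.
#' @param carrier_band `(low, high)` Hz band of the EMG-like carrier noise;
#'   must lie below Nyquist.
#' @param snr_db Plateau signal-to-baseline-noise ratio in dB.
#' @param n_trials_per_gesture Trials generated per gesture.
#' @param seed Master seed; per-trial streams are derived from
#'   `(seed, gesture, trial)` so generation order does not matter.
#' @param sigma_px Isotropic width (pixels) of the Gaussian activation bump.
#' @param drift_px_s Column-axis drift speed (pixels/s) of dynamic gesture
#'   templates; the drift path must fit the grid width.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(G = 8L, grid = electrode_grid(8, 16), fs = 1000,
                         trial_s = 3, activity_fraction = c(1 / 3, 2 / 3),
                         carrier_band = c(20, 400), snr_db = 20,
                         n_trials_per_gesture = 10L, seed = 1L,
                         sigma_px = 1.5, drift_px_s = 4) {
  stopifnot(G >= 2, activity_fraction[1] >= 0,
            activity_fraction[1] < activity_fraction[2],
            activity_fraction[2] <= 1, is.finite(snr_db))
  if (carrier_band[2] >= fs / 2) stop("carrier band exceeds the Nyquist frequency")
  structure(list(G = as.integer(G), grid = grid, fs = fs, trial_s = trial_s,
                 activity_fraction = activity_fraction,
                 carrier_band = carrier_band, snr_db = snr_db,
                 n_trials_per_gesture = as.integer(n_trials_per_gesture),
                 seed = as.integer(seed), sigma_px = sigma_px,
                 drift_px_s = drift_px_s),
            class = "synth_config")
}

# Deterministic greedy farthest-point placement of n centers on the grid
# interior (margin pixels away from the edges; a length-2 margin is
# (rows, cols)).
place_centers <- function(grid, n, margin = 1.5) {
  if (length(margin) == 1) margin <- c(margin, margin)
  # margins shrink on small grids so a center always fits mid-grid
  mr <- min(margin[1], (grid$rows - 1) / 3)
  mc <- min(margin[2], (grid$cols - 1) / 3)
  rr <- seq(mr, grid$rows - 1 - mr, by = 0.5)
  cc <- seq(mc, grid$cols - 1 - mc, by = 0.5)
  if (length(rr) == 0 || length(cc) == 0 || n > length(rr) * length(cc))
    stop("grid too small to place ", n, " distinct activation centers")
  cand <- as.matrix(expand.grid(r = rr, c = cc))
  chosen <- matrix(cand[1, ], 1, 2)  # corner-most candidate
  while (nrow(chosen) < n) {
    dmin <- apply(cand, 1, function(p)
      min(sqrt((p[1] - chosen[, 1])^2 + (p[2] - chosen[, 2])^2)))
    chosen <- rbind(chosen, cand[which.max(dmin), ])
  }
  unname(chosen)
}

gaussian_map <- function(grid, center, sigma) {
  cm <- grid$channel_map
  d2 <- (cm[, 1] - center[1])^2 + (cm[, 2] - center[2])^2
  m <- exp(-d2 / (2 * sigma^2))
  m / sum(m)
}

#' Gesture activation templates
#'
#' Builds `G` gesture templates. Static templates have distinct spatial
#' activation centers (isotropic Gaussian bumps, farthest-point placed) and
#' zero drift. Dynamic templates come in pairs sharing one activation center
#' and drifting along the column axis with opposite velocities. During
#' simulation the whole drift path is translated by a random per-trial
#' offset, so over a trial both members of a pair sweep the same position
#' interval with the same (trapezoidal) dwell-time distribution: a purely
#' spatial single-frame classifier is at chance within a pair by
#' construction, while the displacement across a few consecutive frames
#' reveals the drift direction. (Reflecting the drift at the grid margins
#' would not work: the two reflected trajectories are time-shifted copies of
#' one triangle wave, so even the motion would carry no label information.)
#'
#' @param cfg A [synth_config()].
#' @param dynamic Build drifting (dynamic) templates?
#' @return List of `gesture_template` objects with fields `gesture_id`
#'   (0-based), `center` (the drift-path midpoint for dynamic templates),
#'   `spatial_map` (per-channel weights summing to 1, the bump at `center`),
#'   `drift` (rows/s, cols/s; `(0, 0)` for static templates), `amplitude`.
#' @export
make_gesture_templates <- function(cfg, dynamic = FALSE) {
  g <- cfg$grid
  if (!dynamic) {
    centers <- place_centers(g, cfg$G)
    lapply(seq_len(cfg$G), function(i) {
      structure(list(gesture_id = i - 1L, center = centers[i, ],
                     spatial_map = gaussian_map(g, centers[i, ], cfg$sigma_px),
                     drift = c(0, 0), amplitude = 1),
                class = "gesture_template")
    })
  } else {
    n_centers <- ceiling(cfg$G / 2)
    speed <- cfg$drift_px_s
    t_active <- diff(cfg$activity_fraction) * cfg$trial_s
    half_span <- speed * t_active / 2
    # the path (center +- half_span along columns) must fit the grid interior
    centers <- place_centers(g, n_centers,
                             margin = c(1.5, half_span + 1.5))
    lapply(seq_len(cfg$G), function(i) {
      pair <- (i - 1L) %/% 2L + 1L
      dir <- if ((i - 1L) %% 2L == 0L) 1 else -1
      structure(list(gesture_id = i - 1L, center = centers[pair, ],
                     spatial_map = gaussian_map(g, centers[pair, ], cfg$sigma_px),
                     drift = c(0, dir * speed), amplitude = 1),
                class = "gesture_template")
    })
  }
}

derive_trial_seed <- function(master, gesture_id, trial_idx) {
  as.integer((as.numeric(master) * 100003 + gesture_id * 10007 +
              trial_idx * 101) %% 2147483629)
}

#' Simulate one HD-sEMG trial
#'
#' Each channel's signal is baseline noise plus
#' `envelope(t) * map(channel, t) * carrier(channel, t)`, where the envelope
#' is a rest-ramp-plateau-ramp-rest profile (raised-cosine ramps over 10% of
#' the active duration) occupying the configured activity interval, the map
#' is the template's Gaussian bump following its drift (the drift path is
#' translated by a random per-trial offset within the grid interior, so
#' opposite drift directions sweep identical positions), and the carrier is
#' per-channel Gaussian white noise band-passed to the carrier band and
#' standardized to unit variance. Baseline noise is white with power set by
#' `snr_db` relative to the plateau signal power. Fully reproducible: the
#' RNG stream is derived from `(cfg$seed, gesture_id, trial_idx)`.
#'
#' @param template A `gesture_template` from [make_gesture_templates()].
#' @param cfg A [synth_config()].
#' @param trial_idx 0-based trial index (selects the RNG stream).
#' @return An [recording()] whose `meta` records gesture, trial, seed and the
#'   ground-truth `onset_frame` / `offset_frame` (0-based, half-open).
#' @export
simulate_trial <- function(template, cfg, trial_idx = 0L) {
  g <- cfg$grid
  nch <- g$rows * g$cols
  N <- round(cfg$trial_s * cfg$fs)
  seed <- derive_trial_seed(cfg$seed, template$gesture_id, trial_idx)
  set.seed(seed)

  onset <- round(cfg$activity_fraction[1] * N)
  offset <- round(cfg$activity_fraction[2] * N)
  active_len <- offset - onset
  ramp <- max(1, round(0.1 * active_len))
  env <- numeric(N)
  idx <- seq_len(active_len)
  prof <- rep(1, active_len)
  prof[idx <= ramp] <- 0.5 * (1 - cos(pi * idx[idx <= ramp] / ramp))
  tailing <- idx > active_len - ramp
  prof[tailing] <- 0.5 * (1 - cos(pi * (active_len - idx[tailing] + 1) / ramp))
  env[(onset + 1):offset] <- prof

  # per-channel band-limited unit-variance carrier
  carrier <- matrix(rnorm(nch * N), nch, N)
  carrier <- bandpass_zero_lag(carrier, cfg$fs, cfg$carrier_band[1],
                               cfg$carrier_band[2])
  carrier <- carrier / apply(carrier, 1, stats::sd)

  # activation map over time (channels x frames), following the motion
  tsec <- (seq_len(N) - 1) / cfg$fs
  t_act <- pmin(pmax(tsec - onset / cfg$fs, 0), active_len / cfg$fs)
  T_act <- active_len / cfg$fs
  if (any(template$drift != 0)) {
    # drift path centered on the template center, translated by a random
    # per-trial offset within the grid interior: both drift directions sweep
    # the same positions over a trial, so single frames carry no label
    margin <- 1.0
    half <- abs(template$drift) * T_act / 2
    lo <- c(margin, margin) + half
    hi <- c(g$rows - 1 - margin, g$cols - 1 - margin) - half
    delta <- c(0, 0)
    for (ax in 1:2) if (template$drift[ax] != 0) {
      slack_lo <- lo[ax] - template$center[ax]
      slack_hi <- hi[ax] - template$center[ax]
      if (slack_hi < slack_lo) stop("drift path does not fit the grid")
      delta[ax] <- runif(1, slack_lo, slack_hi)
    }
    rpath <- template$center[1] + delta[1] + template$drift[1] * (t_act - T_act / 2)
    cpath <- template$center[2] + delta[2] + template$drift[2] * (t_act - T_act / 2)
  } else {
    rpath <- rep(template$center[1], N)
    cpath <- rep(template$center[2], N)
  }
  cm <- g$channel_map
  d2 <- outer(cm[, 1], rpath, `-`)^2 + outer(cm[, 2], cpath, `-`)^2
  map <- exp(-d2 / (2 * cfg$sigma_px^2))
  map <- map / rep(colSums(map), each = nch)

  sig <- template$amplitude * map * carrier *
    rep(env, each = nch)
  plateau <- env >= 0.999
  p_sig <- mean(sig[, plateau, drop = FALSE]^2)
  noise_sd <- sqrt(p_sig) / 10^(cfg$snr_db / 20)
  sig <- sig + matrix(rnorm(nch * N, sd = noise_sd), nch, N)

  recording(sig, cfg$fs, g,
            meta = list(gesture = template$gesture_id, trial = trial_idx,
                        seed = seed, onset_frame = onset, offset_frame = offset,
                        dynamic = any(template$drift != 0)))
}

#' Generate a labeled synthetic benchmark
#'
#' `G * n_trials_per_gesture` trials with balanced classes; per-trial RNG
#' streams are derived from the master seed, so two calls with the same
#' configuration produce identical data.
#'
#' @param cfg A [synth_config()].
#' @param dynamic Use dynamic (drifting) gesture templates?
#' @return List of labeled [recording()]s, ordered gesture-major.
#' @export
make_benchmark <- function(cfg, dynamic = FALSE) {
  templates <- make_gesture_templates(cfg, dynamic)
  out <- vector("list", cfg$G * cfg$n_trials_per_gesture)
  i <- 1L
  for (tm in templates)
    for (tr in seq_len(cfg$n_trials_per_gesture) - 1L) {
      out[[i]] <- simulate_trial(tm, cfg, tr)
      i <- i + 1L
    }
  out
}

#' Write a benchmark manifest
#'
#' CSV listing trial id, gesture, RNG seed and ground-truth activity bounds
#' for a list of simulated recordings.
#'
#' @param trials List of recordings from [make_benchmark()].
#' @param path Output CSV path.
#' @export
write_manifest <- function(trials, path) {
  df <- do.call(rbind, lapply(seq_along(trials), function(i) {
    m <- trials[[i]]$meta
    data.frame(trial_id = i - 1L, gesture = m$gesture, trial = m$trial,
               seed = m$seed, onset_frame = m$onset_frame,
               offset_frame = m$offset_frame)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-frame nearest-template baseline classifier
#'
#' A deliberately spatial-only baseline: each frame's rectified deviation
#' from the resting level (|image - 0.5|) is scored against every template's
#' spatial map, the frame votes for the best-matching template, and the trial
#' decision is the majority over frames. Static gestures with distinct
#' centers are separable this way; dynamic gesture pairs sharing a center are
#' indistinguishable to it by construction.
#'
#' @param sequences List of labeled [image_sequence()]s.
#' @param templates Templates from [make_gesture_templates()].
#' @param grid The [electrode_grid()] the sequences were formed on.
#' @return Accuracy percentage over the trials.
#' @export
nearest_template_baseline <- function(sequences, templates, grid) {
  ok <- 0
  for (s in sequences) {
    d <- dim(s$frames)
    feat <- abs(matrix(s$frames, nrow = d[1]) - 0.5)  # frames x pixels
    # template maps in pixel order matching the flattened frames
    scores <- vapply(templates, function(tm) {
      img <- matrix(NA_real_, grid$rows, grid$cols)
      cmap <- grid$channel_map
      img[cbind(cmap[, 1] + 1, cmap[, 2] + 1)] <- tm$spatial_map
      as.vector(feat %*% as.vector(img))
    }, numeric(d[1]))
    votes <- max.col(scores, ties.method = "first") - 1L
    ok <- ok + (majority_vote(votes) == s$label)
  }
  100 * ok / length(sequences)
}
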