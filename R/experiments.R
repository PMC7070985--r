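#' Preprocess a raw trial into a labeled image sequence
#'
#' The CSL-style conditioning chain: zero-lag Butterworth band-pass, rectified
#' intensity envelope, windowed threshold segmentation, linear normalization
#' of the band-passed signal to `[0, 1]`, and image-sequence formation over
#' the detected activity segment. CapgMyo-style data that is already
#' segmented and scaled to `[-1, 1]` should instead use
#' `style = "capgmyo"`, which only applies [normalize_unit_interval()] and
#' keeps the whole trial.
#'
#' @param rec A raw [recording()].
#' @param style `"csl"` (filter + segment) or `"capgmyo"` (normalize only).
#' @param band Band-pass edges in Hz for the `"csl"` chain.
#' @param window_len Segmentation window in frames.
#' @return A labeled [image_sequence()].
#' @export
prepare_sequence <- function(rec, style = c("csl", "capgmyo"),
                             band = c(20, 400), window_len = 150L) {
  style <- match.arg(style)
  if (style == "capgmyo") {
    norm <- recording(normalize_unit_interval(rec$signal, c(-1, 1)),
                      rec$fs, rec$grid, rec$meta)
    return(build_image_sequence(norm))
  }
  filt <- bandpass_zero_lag(rec$signal, rec$fs, band[1], band[2])
  env <- intensity_envelope(filt, rec$fs)
  seg <- segment_activity(env, window_len)
  norm <- recording(normalize_unit_interval(filt), rec$fs, rec$grid, rec$meta)
  build_image_sequence(norm, seg)
}

#' Experiment configuration
#'
#' Bundles everything needed to run one desk-scale recognition experiment on
#' synthetic data: the generator settings, the evaluation protocol, cube and
#' network geometry, and the training recipe. Pooling defaults follow the
#' grid geometry convention (temporal pool 2 for 1000 Hz-style data, 4 for
#' 2048 Hz-style data).
#'
#' @param synth A [synth_config()].
#' @param dynamic Use dynamic gesture templates?
#' @param protocol `"capgmyo-half-half"` or `"csl-leave-one-out"`.
#' @param l_cube Frames per cube for the 3D network.
#' @param train_stride Cube-extraction stride on training trials (test trials
#'   always use non-overlapping cubes).
#' @param frame_stride Frame subsampling stride for 2D training.
#' @param pool_s Temporal pooling size.
#' @param voting_grid_ms Voting-window lengths (ms) to sweep.
#' @param band Band-pass edges for preprocessing.
#' @param window_len Segmentation window in frames.
#' @param n_kernels,fc Network size (see [build_3d_cnn()]).
#' @param dropout_p Dropout probability on the hidden dense layers.
#' @param training A [training_config()].
#' @param count_convention Parameter-count convention recorded in reports.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(synth, dynamic = FALSE,
                              protocol = c("capgmyo-half-half", "csl-leave-one-out"),
                              l_cube = 10L, train_stride = 2L, frame_stride = 4L,
                              pool_s = 2L, voting_grid_ms = c(50, 100, 150, 200, 300),
                              band = c(20, 400), window_len = 150L,
                              n_kernels = c(32, 64, 64), fc = c(512, 128),
                              dropout_p = 0.5,
                              training = training_config(),
                              count_convention = "with-statistics") {
  protocol <- match.arg(protocol)
  structure(list(synth = synth, dynamic = dynamic, protocol = protocol,
                 l_cube = as.integer(l_cube), train_stride = as.integer(train_stride),
                 frame_stride = as.integer(frame_stride), pool_s = as.integer(pool_s),
                 voting_grid_ms = voting_grid_ms, band = band,
                 window_len = as.integer(window_len), n_kernels = n_kernels,
                 fc = fc, dropout_p = dropout_p, training = training,
                 count_convention = count_convention),
            class = "experiment_config")
}

# group a flat gesture-major trial list into per-gesture trial lists
group_by_gesture <- function(sequences) {
  labs <- vapply(sequences, `[[`, integer(1), "label")
  lapply(sort(unique(labs)), function(g) sequences[labs == g])
}

train_test_split <- function(sequences, protocol, k = NULL) {
  groups <- group_by_gesture(sequences)
  tr <- list(); te <- list()
  for (grp in groups) {
    sp <- if (protocol == "capgmyo-half-half") split_trials(grp, "half-half-by-trial")
          else split_trials(grp, "leave-one-trial-out", k = k)
    tr <- c(tr, sp$train); te <- c(te, sp$test)
  }
  list(train = tr, test = te)
}

cubes_from_sequences <- function(sequences, l, stride, origin) {
  bind_cubes(lapply(sequences, extract_cubes, l = l, stride = stride,
                    origin = origin))
}

fit_and_evaluate <- function(cfg, train_seqs, test_seqs) {
  hw <- c(dim(train_seqs[[1]]$frames)[2], dim(train_seqs[[1]]$frames)[3])
  G <- cfg$synth$G
  fs <- train_seqs[[1]]$fs

  spec3 <- build_3d_cnn(c(cfg$l_cube, hw), pool_s = cfg$pool_s, G = G,
                        n_kernels = cfg$n_kernels, fc = cfg$fc,
                        dropout_p = cfg$dropout_p)
  train3 <- cubes_from_sequences(train_seqs, cfg$l_cube, cfg$train_stride, "train")
  model3 <- fit_network(spec3, train3, cfg$training)

  spec2 <- build_2d_cnn(hw, G = G, n_kernels = cfg$n_kernels, fc = cfg$fc,
                        dropout_p = cfg$dropout_p)
  train2 <- cubes_from_sequences(train_seqs, 1L, cfg$frame_stride, "train")
  model2 <- fit_network(spec2, train2, cfg$training)

  t_cube_ms <- 1000 * cfg$l_cube / fs
  sweep3 <- accuracy_vs_window_sweep(model3, test_seqs, cfg$l_cube,
                                     sort(unique(c(t_cube_ms, cfg$voting_grid_ms))))
  sweep2 <- accuracy_vs_window_sweep(model2, test_seqs, 1L,
                                     sort(unique(c(t_cube_ms, cfg$voting_grid_ms))))
  vote_ms <- max(cfg$voting_grid_ms)
  ev3 <- evaluate_voted(model3, test_seqs, cfg$l_cube, vote_ms)
  ev2 <- evaluate_voted(model2, test_seqs, 1L, vote_ms)
  # the head-to-head comparison at equal temporal context: one cube of the 3D
  # network vs the same time span of voted 2D frame predictions
  acc3_cube <- sweep3$accuracy_pct[sweep3$window_ms == t_cube_ms]
  acc2_cube <- sweep2$accuracy_pct[sweep2$window_ms == t_cube_ms]
  list(model3 = model3, model2 = model2,
       sweep3 = sweep3, sweep2 = sweep2,
       voted3 = ev3, voted2 = ev2,
       acc3_per_cube = acc3_cube, acc2_frame_mv = acc2_cube,
       t_cube_ms = t_cube_ms)
}

#' Run a full recognition protocol on synthetic data
#'
#' Generates a synthetic benchmark, preprocesses every trial, splits into
#' training and testing per the protocol, trains both the 3D CNN and its 2D
#' ablation, and evaluates majority-voted accuracies over the voting-window
#' grid. Produces accuracy-vs-window tables for both models, confusion
#' matrices at the longest voting window, a parameter-count table, and a JSON
#' report with all seeds and decisions. For `"csl-leave-one-out"`, `folds`
#' selects which held-out trial indices to run (all by default).
#'
#' @param cfg An [experiment_config()].
#' @param out_dir Optional output directory for TSV/CSV/JSON artifacts.
#' @param folds For leave-one-out: 0-based held-out trial indices to run.
#' @param verbose Print progress.
#' @return A report list (invisibly written to `out_dir` when given).
#' @export
run_protocol <- function(cfg, out_dir = NULL, folds = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  # fail on config inconsistencies before any training
  hw <- c(cfg$synth$grid$rows, cfg$synth$grid$cols)
  build_3d_cnn(c(cfg$l_cube, hw), pool_s = cfg$pool_s, G = cfg$synth$G,
               n_kernels = cfg$n_kernels, fc = cfg$fc, dropout_p = cfg$dropout_p)

  if (verbose) message("simulating ", cfg$synth$G * cfg$synth$n_trials_per_gesture,
                       " trials")
  recs <- make_benchmark(cfg$synth, dynamic = cfg$dynamic)
  seqs <- lapply(recs, prepare_sequence, style = "csl", band = cfg$band,
                 window_len = cfg$window_len)

  results <- list()
  if (cfg$protocol == "capgmyo-half-half") {
    sp <- train_test_split(seqs, cfg$protocol)
    if (verbose) message("training (", length(sp$train), " train trials)")
    results[["half-half"]] <- fit_and_evaluate(cfg, sp$train, sp$test)
  } else {
    if (is.null(folds)) folds <- seq_len(cfg$synth$n_trials_per_gesture) - 1L
    for (k in folds) {
      if (verbose) message("fold ", k)
      sp <- train_test_split(seqs, cfg$protocol, k = k)
      results[[paste0("fold", k)]] <- fit_and_evaluate(cfg, sp$train, sp$test)
    }
  }

  counts <- data.frame(
    model = c("3d", "2d"),
    parameters = c(count_parameters(build_3d_cnn(c(cfg$l_cube, hw), cfg$pool_s,
                                                 cfg$synth$G, cfg$n_kernels, cfg$fc),
                                    cfg$count_convention),
                   count_parameters(build_2d_cnn(hw, cfg$synth$G, cfg$n_kernels,
                                                 cfg$fc),
                                    cfg$count_convention)))

  pool_acc <- function(field)
    mean(vapply(results, function(r) r[[field]]$accuracy, numeric(1)))
  report <- list(
    protocol = cfg$protocol,
    dynamic = cfg$dynamic,
    seed = cfg$synth$seed,
    train_seed = cfg$training$seed,
    l_cube = cfg$l_cube,
    t_cube_ms = results[[1]]$t_cube_ms,
    count_convention = cfg$count_convention,
    parameter_counts = counts,
    voted_accuracy_3d = pool_acc("voted3"),
    voted_accuracy_2d = pool_acc("voted2"),
    per_cube_accuracy_3d = mean(vapply(results, `[[`, numeric(1), "acc3_per_cube")),
    frame_mv_accuracy_2d = mean(vapply(results, `[[`, numeric(1), "acc2_frame_mv")),
    decisions = list(tie_break = "most-recent", voting_windows = "non-overlapping",
                     threshold_rule = "strict-greater", segment_rule = "longest-run"),
    results = results)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(results)) {
      r <- results[[nm]]
      utils::write.table(r$sweep3, file.path(out_dir, paste0(nm, "_sweep_3d.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(r$sweep2, file.path(out_dir, paste0(nm, "_sweep_2d.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      write_confusion(r$voted3$confusion,
                      file.path(out_dir, paste0(nm, "_confusion_3d.csv")))
      write_confusion(r$voted2$confusion,
                      file.path(out_dir, paste0(nm, "_confusion_2d.csv")))
    }
    utils::write.table(counts, file.path(out_dir, "parameter_counts.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    slim <- report[setdiff(names(report), "results")]
    jsonlite::write_json(slim, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' Weight-count table over sliding-window lengths
#'
#' One analytic parameter count per cube length `l` and count convention for
#' a dataset geometry: `"capgmyo"` is an 8 x 16 grid, 8 gestures, temporal
#' pooling 2; `"csl"` is a 7 x 24 grid, 27 gestures, temporal pooling 4. 2D
#' counts do not depend on `l` and are reported alongside. An `l` whose
#' temporal dimension collapses is flagged with `NA` rather than aborting the
#' table.
#'
#' @param l_values Cube lengths in frames.
#' @param geometry `"capgmyo"` or `"csl"`.
#' @param conventions Count-convention tags to report.
#' @return `data.frame` with one row per `l` per convention.
#' @export
report_table1 <- function(l_values, geometry = c("capgmyo", "csl"),
                          conventions = c("trainable", "with-statistics")) {
  geometry <- match.arg(geometry)
  hw <- if (geometry == "capgmyo") c(8L, 16L) else c(7L, 24L)
  G <- if (geometry == "capgmyo") 8L else 27L
  pool_s <- if (geometry == "capgmyo") 2L else 4L
  rows <- list()
  for (l in l_values) for (cv in conventions) {
    cnt3 <- tryCatch(count_parameters(build_3d_cnn(c(l, hw), pool_s, G), cv),
                     error = function(e) NA_real_)
    cnt2 <- count_parameters(build_2d_cnn(hw, G), cv)
    rows[[length(rows) + 1]] <-
      data.frame(geometry = geometry, l_frames = l, l_ms = NA_real_,
                 convention = cv, params_3d = cnt3, params_2d = cnt2)
  }
  out <- do.call(rbind, rows)
  fs <- if (geometry == "capgmyo") 1000 else 2048
  out$l_ms <- 1000 * out$l_frames / fs
  out
}

#' Read an experiment configuration from YAML
#'
#' The file may carry any subset of the [experiment_config()] and
#' [synth_config()] fields under top-level keys `synth`, `experiment` and
#' `training`; unspecified fields keep their defaults. `synth$grid` is given
#' as `[rows, cols]`.
#'
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
experiment_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sargs <- y$synth
  if (!is.null(sargs$grid)) sargs$grid <- electrode_grid(sargs$grid[1], sargs$grid[2])
  synth <- do.call(synth_config, if (is.null(sargs)) list() else sargs)
  targs <- if (is.null(y$training)) list() else y$training
  training <- do.call(training_config, targs)
  eargs <- if (is.null(y$experiment)) list() else y$experiment
  eargs$synth <- synth
  eargs$training <- training
  do.call(experiment_config, eargs)
}

#' Canonical desk-scale benchmark configurations
#'
#' Frozen study conditions for the two synthetic end-to-end experiments. The
#' static benchmark emulates CapgMyo-style content: four gestures with
#' distinct activation centers on an 8 x 16 grid at 1000 Hz, 3-second trials
#' with 1 second of activity, 10 dB plateau SNR, 6 trials per gesture,
#' 10-frame cubes, and a scaled-down network (8/16/16 kernels, 64/32 dense)
#' sized for single-CPU training. The dynamic benchmark emulates CSL-style
#' dynamic content where spatial information alone is insufficient: four
#' gestures sharing activation centers pairwise and differing only in drift
#' direction (4 px/s along the columns, path start randomized per trial), on
#' an 8 x 16 grid at 256 Hz with a 20-100 Hz carrier, 4-second trials with 2
#' seconds of activity, 128-frame cubes (500 ms, a 2-pixel displacement), and
#' a 4/8/8-kernel network without dense-layer dropout, trained at rate 0.05
#' on densely overlapping cubes (stride 8).
#'
#' @param seed Master seed for generation and training.
#' @return An [experiment_config()].
#' @export
static_benchmark_config <- function(seed = 1L) {
  experiment_config(
    synth = synth_config(G = 4L, grid = electrode_grid(8, 16), fs = 1000,
                         trial_s = 3, activity_fraction = c(1 / 3, 2 / 3),
                         carrier_band = c(20, 400), snr_db = 10,
                         n_trials_per_gesture = 10L, seed = seed),
    dynamic = FALSE, protocol = "capgmyo-half-half",
    l_cube = 10L, train_stride = 25L, frame_stride = 10L, pool_s = 2L,
    voting_grid_ms = c(50, 100, 150), band = c(20, 400), window_len = 150L,
    n_kernels = c(8, 16, 16), fc = c(64, 32),
    training = training_config(lr0 = 0.1, batch_size = 32L, max_epochs = 15L,
                               seed = seed))
}

#' @rdname static_benchmark_config
#' @export
dynamic_benchmark_config <- function(seed = 1L) {
  experiment_config(
    synth = synth_config(G = 4L, grid = electrode_grid(8, 16), fs = 256,
                         trial_s = 4, activity_fraction = c(0.25, 0.75),
                         carrier_band = c(20, 100), snr_db = 10,
                         n_trials_per_gesture = 6L, seed = seed,
                         drift_px_s = 4),
    dynamic = TRUE, protocol = "capgmyo-half-half",
    l_cube = 128L, train_stride = 8L, frame_stride = 4L, pool_s = 4L,
    voting_grid_ms = c(500), band = c(20, 100), window_len = 64L,
    n_kernels = c(4, 8, 8), fc = c(32, 16), dropout_p = 0,
    training = training_config(lr0 = 0.05, batch_size = 32L, max_epochs = 15L,
                               seed = seed))
}
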