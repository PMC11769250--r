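# Declarative run configuration and the end-to-end pipeline:
# simulate (or load) -> band-pass + EOG exclusion -> cue-locked trials ->
# trial-level stratified split -> sliding windows (-> augmentation) ->
# CSP + WPD feature maps -> train (or grid search) -> evaluate -> files.

#' Default run configuration
#'
#' @return nested named list with every supported configuration key; see
#'   the package vignette for the meaning and units of each field.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "mi-results",
    input = NULL,                       # optional recording path (.rds/.gdf)
    synthetic = list(n_eeg_channels = 22L, n_eog_channels = 3L, fs = 250,
                     snr_db = 5, trials_per_class_per_run = 48L,
                     runs_per_session = 6L, trial_length_s = 7.5,
                     cue_onset_s = 2, mi_end_s = 6),
    bandpass = list(low_hz = 7, high_hz = 30, order = 5L),
    trial = list(start_s = 2, end_s = 6),
    window = list(length_s = 2, overlap_frac = 0.5),
    standardize = FALSE,
    split = list(test_frac = 0.2),
    features = list(csp_pairs = 2L, cov_norm = "trace", wavelet = "db4",
                    level = 4L, bands = list(c(8, 30)), time_decim = 1L),
    model = list(n_filters = 16L, dropout = 0.4, weight_decay = 1e-4,
                 pooling = "max", paper_faithful = TRUE),
    train = list(lr = 0.001, batch_size = 32L, epochs = 100L,
                 augment_sigma = 0.1),
    gridsearch = list(enabled = FALSE, lr_grid = c(0.001, 0.005, 0.01),
                      batch_grid = c(16L, 32L, 64L),
                      dropout_grid = c(0.3, 0.4, 0.5), cv_folds = 3L,
                      epochs = 1L)
  )
}

# recursively merge user values over defaults, rejecting unknown keys
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section `", path, "` must be a mapping",
                           call. = FALSE)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, nm, "."))
    } else {
      defaults[nm] <- list(user[[nm]])   # keeps explicit NULLs in place
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML file (or takes a list), fills in [default_run_config()]
#' values and rejects unknown keys. Scalar overrides for `seed` and
#' `out_dir` win over the file.
#'
#' @param config path to a YAML file, a named list, or `NULL` for defaults.
#' @param seed optional seed override.
#' @param out_dir optional output-directory override.
#' @return validated configuration list of class `run_config`.
#' @export
run_config <- function(config = NULL, seed = NULL, out_dir = NULL) {
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- merge_config(default_run_config(), user)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  w <- cfg$window
  if (!(w$overlap_frac >= 0 && w$overlap_frac < 1))
    stop("invalid `window.overlap_frac`: must lie in [0, 1)", call. = FALSE)
  if (cfg$split$test_frac <= 0 || cfg$split$test_frac >= 1)
    stop("invalid `split.test_frac`: must lie in (0, 1)", call. = FALSE)
  # normalize band list shape (YAML gives list of 2-vectors or a flat pair)
  if (!is.list(cfg$features$bands)) cfg$features$bands <- list(cfg$features$bands)
  structure(cfg, class = c("run_config", "list"))
}

# stratified split of trials into train/test window sets
split_trials <- function(trials, test_frac, seed) {
  labs <- trials$labels
  with_preserved_rng({
    set.seed(seed)
    test_idx <- unlist(lapply(unique(labs), function(cl) {
      idx <- which(labs == cl)
      sample(idx, max(1L, round(length(idx) * test_frac)))
    }))
  })
  list(train = epoch_subset(trials, setdiff(seq_along(labs), test_idx)),
       test = epoch_subset(trials, sort(test_idx)))
}

# concatenate two epoch sets (same geometry)
epoch_concat <- function(a, b) {
  stopifnot(identical(dim(a$data)[2:3], dim(b$data)[2:3]), a$fs == b$fs)
  d <- dim(a$data)
  dat <- array(0, c(d[1] + dim(b$data)[1], d[2], d[3]))
  dat[seq_len(d[1]), , ] <- a$data
  dat[d[1] + seq_len(dim(b$data)[1]), , ] <- b$data
  epoch_set(dat, c(a$labels, b$labels), a$fs,
            rbind(a$provenance, b$provenance), a$channel_labels)
}

write_metrics_files <- function(out_dir, metrics, trial_metrics, history,
                                cv_table = NULL) {
  mj <- list(
    window = list(accuracy = metrics$accuracy,
                  macro_precision = metrics$macro_precision,
                  macro_recall = metrics$macro_recall,
                  macro_f1 = metrics$macro_f1,
                  per_class = metrics$per_class, n = metrics$n),
    trial = list(accuracy = trial_metrics$accuracy, n = trial_metrics$n)
  )
  jsonlite::write_json(mj, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(metrics$confusion, file.path(out_dir, "confusion.csv"))
  utils::write.csv(history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  if (!is.null(cv_table))
    utils::write.csv(cv_table, file.path(out_dir, "cv_table.csv"),
                     row.names = FALSE)
}

#' Run the full pipeline from one configuration
#'
#' Executes simulate (or load) -> preprocess -> features -> train (or grid
#' search) -> evaluate, writing metrics, confusion matrix, training curves,
#' the normalized configuration and a manifest into `out_dir`. Idempotent
#' for a fixed seed. A manifest is written even when a stage fails, with
#' the failing stage recorded.
#'
#' @param config a [run_config()] (or anything it accepts).
#' @param seed optional seed override.
#' @param out_dir optional output-directory override.
#' @param verbose print stage progress (default `TRUE`).
#' @return invisible list with the recording, epoch sets, fitted CSP model,
#'   trained fusion model, history and metrics.
#' @export
run_all <- function(config = NULL, seed = NULL, out_dir = NULL,
                    verbose = TRUE) {
  cfg <- run_config(config, seed, out_dir)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(cfg$out_dir, "config.yaml"))
  manifest <- list(
    package = "misynergy",
    package_version = as.character(utils::packageVersion("misynergy")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(file.path(cfg$out_dir, "config.yaml"))),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list()
  )
  say <- function(...) if (verbose) message("[mi-synergy] ", ...)
  finish_manifest <- function() {
    manifest$finished <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  stage <- function(name, expr) {
    say("stage: ", name)
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- "failed"
      manifest$error <<- conditionMessage(e)
      finish_manifest()
      stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <- "ok"
    res
  }

  rec <- stage("simulate", {
    if (!is.null(cfg$input)) {
      if (grepl("\\.gdf$", cfg$input, ignore.case = TRUE)) read_gdf(cfg$input)
      else load_recording(cfg$input)
    } else {
      sy <- cfg$synthetic
      simulate_recording(synthetic_spec(
        n_eeg_channels = sy$n_eeg_channels, n_eog_channels = sy$n_eog_channels,
        fs = sy$fs, snr_db = sy$snr_db,
        trials_per_class_per_run = sy$trials_per_class_per_run,
        runs_per_session = sy$runs_per_session,
        trial_length_s = sy$trial_length_s, cue_onset_s = sy$cue_onset_s,
        mi_end_s = sy$mi_end_s, seed = cfg$seed))
    }
  })

  prep <- stage("preprocess", {
    x <- bandpass(rec, bandpass_spec(cfg$bandpass$low_hz, cfg$bandpass$high_hz,
                                     cfg$bandpass$order))
    x <- drop_eog(x)
    trials <- extract_trials(x, cfg$trial$start_s, cfg$trial$end_s)
    sp <- split_trials(trials, cfg$split$test_frac, cfg$seed)
    ws <- window_spec(cfg$window$length_s, cfg$window$overlap_frac)
    train_w <- slide_windows(sp$train, ws)
    test_w <- slide_windows(sp$test, ws)
    if (isTRUE(cfg$standardize)) {
      train_w <- standardize_windows(train_w)
      test_w <- standardize_windows(test_w)
    }
    if (cfg$train$augment_sigma > 0)
      train_w <- epoch_concat(train_w,
                              augment_noise(train_w, cfg$train$augment_sigma,
                                            seed = cfg$seed + 1L))
    list(train = train_w, test = test_w)
  })

  feats <- stage("features", {
    fe <- cfg$features
    csp <- csp_fit(prep$train, n_pairs = fe$csp_pairs, cov_norm = fe$cov_norm)
    wpd <- if (fe$level > 0) wpd_spec(fe$wavelet, fe$level, fe$bands) else NULL
    fm_train <- build_feature_map(prep$train, csp, wpd, fe$time_decim)
    fm_test <- build_feature_map(prep$test, csp, wpd, fe$time_decim,
                                 scaler = fm_train$scaler)
    list(csp = csp, wpd = wpd, train = fm_train, test = fm_test)
  })

  cv_table <- NULL
  hyper <- list(lr = cfg$train$lr, batch_size = cfg$train$batch_size,
                dropout = cfg$model$dropout)
  if (isTRUE(cfg$gridsearch$enabled)) {
    gs <- stage("gridsearch", {
      gcfg <- train_config(cfg$gridsearch$lr_grid, cfg$gridsearch$batch_grid,
                           cfg$gridsearch$dropout_grid,
                           epochs = cfg$gridsearch$epochs,
                           cv_folds = cfg$gridsearch$cv_folds,
                           seed = cfg$seed)
      grid_search(prep$train, gcfg,
                  fusion_config(n_filters = cfg$model$n_filters,
                                dropout = cfg$model$dropout,
                                weight_decay = cfg$model$weight_decay,
                                pooling = cfg$model$pooling,
                                paper_faithful = cfg$model$paper_faithful,
                                seed = cfg$seed),
                  csp_pairs = cfg$features$csp_pairs,
                  wpd = feats$wpd, time_decim = cfg$features$time_decim)
    })
    hyper <- gs$best
    cv_table <- gs$table
  }

  fit <- stage("train", {
    mc <- fusion_config(n_filters = cfg$model$n_filters,
                        dropout = hyper$dropout,
                        weight_decay = cfg$model$weight_decay,
                        pooling = cfg$model$pooling,
                        paper_faithful = cfg$model$paper_faithful,
                        seed = cfg$seed)
    mdl <- build_fusion(mc, dim(feats$train$map)[2:3])
    train(mdl, feats$train, epochs = cfg$train$epochs, lr = hyper$lr,
          batch_size = hyper$batch_size, seed = cfg$seed,
          validation = feats$test)
  })

  results <- stage("evaluate", {
    metrics <- evaluate(fit$model, feats$test)
    proba <- predict_proba(fit$model, feats$test)
    votes <- window_vote(proba, feats$test$provenance, feats$test$labels)
    trial_metrics <- compute_metrics(votes$true, votes$pred,
                                     fit$model$config$n_classes)
    write_metrics_files(cfg$out_dir, metrics, trial_metrics, fit$history,
                        cv_table)
    list(window = metrics, trial = trial_metrics)
  })

  finish_manifest()
  say(sprintf("done: window accuracy %.3f, trial accuracy %.3f",
              results$window$accuracy, results$trial$accuracy))
  invisible(list(recording = rec, windows = prep, features = feats,
                 model = fit$model, history = fit$history,
                 metrics = results, hyper = hyper, config = cfg))
}
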