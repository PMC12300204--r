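#' Default pipeline configuration
#'
#' A single nested list drives the whole simulate -> extract -> evaluate
#' pipeline; [run_pipeline()] merges a user config (e.g. from YAML) over
#' these defaults. The numeric defaults are the task standards: 100 stimulus
#' positions shown 1 s each, 4--20 degree jumps, 303-sample windows split
#' into three 100-sample segments, 50 retained positions.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    output_dir = "gazeid-run",
    synth = list(n_subjects = 8, n_sessions = 3, positions = 100,
                 dwell_ms = 1000, amplitude_range = c(4, 20),
                 blink_rate = 0.05),
    segment = list(window_len = 303, segment_len = 100, g = 3, x = 50),
    model = list(kind = "lstm", lstm_units = 64,
                 dense_hidden = c(100, 75, 50), dropout_rate = 0.5),
    train = list(epochs = 150, lr = 0.001, batch_size = 16),
    eval = list(scale_mode = "train")
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file; keys override [default_config()].
#' @return Merged configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop_gazeid(sprintf("config file not found: %s", path), "gazeid_io_error")
  }
  merge_config(default_config(), yaml::read_yaml(path))
}

#' Run the full pipeline on simulated data
#'
#' Simulates a cohort, writes the per-trial CSVs, extracts features, runs the
#' LOSO experiment and writes the evaluation report plus a run manifest
#' (config, seed, package version) to `output_dir`.
#'
#' @param config Configuration list ([default_config()] shape) or a YAML
#'   path.
#' @param stages Character subset of `c("simulate", "extract", "train",
#'   "evaluate")`: `"simulate"` writes the cohort CSVs, `"extract"` persists
#'   the feature dataset ([write_features()]), `"train"` fits one classifier
#'   on all sessions and saves a checkpoint ([save_model()]), `"evaluate"`
#'   runs the LOSO experiment and writes the report.
#' @return The [run_experiment()] report (invisibly `NULL` if evaluation was
#'   not requested).
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "evaluate")) {
  if (is.character(config)) config <- load_config(config)
  if (is.null(config$seed)) {
    stop_gazeid("config must set a seed", "gazeid_validation_error")
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  schedule <- generate_schedule(count = config$synth$positions,
                                dwell_ms = config$synth$dwell_ms,
                                amplitude_range = config$synth$amplitude_range,
                                seed = config$seed)
  profiles <- random_profiles(config$synth$n_subjects,
                              blink_rate = config$synth$blink_rate,
                              seed = config$seed + 1)
  cohort <- simulate_cohort(profiles, config$synth$n_sessions, schedule,
                            seed = config$seed + 2)
  if ("simulate" %in% stages) {
    data_dir <- file.path(config$output_dir, "recordings")
    dir.create(data_dir, showWarnings = FALSE)
    for (rec in cohort$recordings) {
      write_gaze_csv(rec, file.path(data_dir,
                                    sprintf("%s_session%s.csv",
                                            rec$subject_id, rec$session_id)))
    }
  }
  report <- NULL
  needs_features <- any(c("extract", "train", "evaluate") %in% stages)
  if (needs_features) {
    features <- build_feature_dataset(cohort$recordings, schedule,
                                      x_count = config$segment$x,
                                      g = config$segment$g,
                                      segment_len = config$segment$segment_len,
                                      window_len = config$segment$window_len)
    spec <- model_spec(kind = config$model$kind,
                       num_labels = config$synth$n_subjects,
                       lstm_units = config$model$lstm_units,
                       dense_hidden = config$model$dense_hidden,
                       dropout_rate = config$model$dropout_rate,
                       timesteps = config$segment$segment_len)
    cfg <- train_config(epochs = config$train$epochs, lr = config$train$lr,
                        batch_size = config$train$batch_size,
                        seed = config$seed)
    if ("extract" %in% stages) {
      write_features(features, file.path(config$output_dir, "features"))
    }
    if ("train" %in% stages) {
      scaled <- apply_scalers(features$ts, fit_scalers(features$ts))
      x <- if (spec$kind == "lstm") scaled else stat_matrix(scaled)
      subjects <- sort(unique(features$meta$subject))
      y <- match(features$meta$subject, subjects)
      model <- train_model(build_model(spec, seed = config$seed), x, y, cfg)
      save_model(model, file.path(config$output_dir, "model.rds"))
    }
    if ("evaluate" %in% stages) {
      report <- run_experiment(features, spec, cfg,
                               scale_mode = config$eval$scale_mode)
      write_report(report, config$output_dir)
    }
  }
  manifest <- list(seed = config$seed, config = config,
                   package_version = as.character(utils::packageVersion("gazeid")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
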