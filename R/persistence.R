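#' Persist a feature dataset as CSV
#'
#' Writes two files: `<prefix>-manifest.csv` with one row of provenance per
#' sample (subject, session, position, segment) and `<prefix>-ts.csv` with
#' the unscaled channel matrix of each sample flattened row-wise
#' (`t001_v, t001_a, ..., t100_Ft`). Plain text keeps the artefacts
#' diff-able and tool-agnostic.
#'
#' @param features A [build_feature_dataset()] result.
#' @param prefix Output path prefix (directories are created).
#' @return Invisibly, the two paths written.
#' @export
write_features <- function(features, prefix) {
  stopifnot(inherits(features, "gaze_features"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  manifest_path <- paste0(prefix, "-manifest.csv")
  ts_path <- paste0(prefix, "-ts.csv")
  utils::write.csv(features$meta, manifest_path, row.names = FALSE)
  dims <- dim(features$ts)
  channels <- dimnames(features$ts)[[3]]
  flat <- matrix(aperm(features$ts, c(1, 3, 2)), nrow = dims[1])
  colnames(flat) <- as.vector(vapply(seq_len(dims[2]), function(t)
    sprintf("t%03d_%s", t, channels), character(length(channels))))
  utils::write.csv(flat, ts_path, row.names = FALSE)
  invisible(c(manifest = manifest_path, ts = ts_path))
}

#' Read back a persisted feature dataset
#'
#' @param prefix Path prefix used by [write_features()].
#' @return A `gaze_features` object equivalent to the one written (metadata
#'   fields derived from the manifest).
#' @export
read_features <- function(prefix) {
  manifest_path <- paste0(prefix, "-manifest.csv")
  ts_path <- paste0(prefix, "-ts.csv")
  if (!file.exists(manifest_path) || !file.exists(ts_path)) {
    stop_gazeid(sprintf("no feature files at prefix %s", prefix),
                "gazeid_io_error")
  }
  meta <- utils::read.csv(manifest_path, stringsAsFactors = FALSE,
                          colClasses = c(subject = "character",
                                         session = "character"))
  flat <- as.matrix(utils::read.csv(ts_path, check.names = FALSE))
  channels <- unique(sub("^t[0-9]+_", "", colnames(flat)))
  n_time <- ncol(flat) / length(channels)
  ts <- aperm(array(flat, dim = c(nrow(flat), length(channels), n_time)),
              c(1, 3, 2))
  dimnames(ts) <- list(NULL, NULL, channels)
  structure(list(ts = ts, meta = meta,
                 positions = sort(unique(meta$position)),
                 g = max(meta$segment), segment_len = n_time,
                 x_count = length(unique(meta$position))),
            class = "gaze_features")
}

#' Save a trained classifier
#'
#' The model is serialised with `saveRDS()`; a human-readable JSON sidecar
#' (`<path>.json`) records the architecture specification and the training
#' loss trace.
#'
#' @param model A [build_model()]/[train_model()] result.
#' @param path Output path for the checkpoint (conventionally `.rds`).
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "gazeid_model"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, path)
  jsonlite::write_json(list(spec = unclass(model$spec),
                            trained = model$trained,
                            epochs = length(model$loss_trace),
                            final_loss = if (model$trained)
                              model$loss_trace[length(model$loss_trace)]
                            else NULL),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a saved classifier
#'
#' @param path Path given to [save_model()].
#' @return The `gazeid_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    stop_gazeid(sprintf("no model checkpoint at %s", path), "gazeid_io_error")
  }
  model <- readRDS(path)
  if (!inherits(model, "gazeid_model")) {
    stop_gazeid("file is not a gazeid model checkpoint", "gazeid_format_error")
  }
  model
}
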