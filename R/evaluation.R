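#' Experiment design bookkeeping
#'
#' Sizes of a jumping-point identification experiment: `S` sessions, `U`
#' participants (one identity label each, so `l = U`), `X` stimulus positions
#' retained per trial and `G` segments per position. Each participant then
#' contributes `FVn = G * X` feature vectors per session and
#' `T_FVn = S * FVn` in total.
#'
#' @param S Number of sessions.
#' @param U Number of participants.
#' @param X Stimulus positions per trial.
#' @param G Segments per position.
#' @return An object of class `experiment_design` with derived counts `l`,
#'   `fvn`, `t_fvn`.
#' @export
experiment_design <- function(S, U, X, G = 3) {
  if (any(c(S, U, X, G) < 1)) {
    stop_gazeid("all design counts must be >= 1", "gazeid_validation_error")
  }
  structure(list(S = as.integer(S), U = as.integer(U), X = as.integer(X),
                 G = as.integer(G), l = as.integer(U),
                 fvn = as.integer(G * X), t_fvn = as.integer(S * G * X)),
            class = "experiment_design")
}

#' Sample counts of a design
#'
#' Total number of feature vectors and the train/test split sizes of one
#' leave-one-session-out fold: the held-out session contributes `U * X * G`
#' test samples and the remaining `S - 1` sessions the rest.
#'
#' @param design An [experiment_design()].
#' @return Named numeric vector `total`, `train`, `test`.
#' @export
sample_counts <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  total <- design$S * design$U * design$X * design$G
  test <- design$U * design$X * design$G
  c(total = total, train = total - test, test = test)
}

#' Leave-One-Session-Out fold assignment
#'
#' One fold per session: fold `i`'s test set is every sample of session `i`,
#' its training set every other sample. Folds partition the data.
#'
#' @param meta Data frame with a `session` column (one row per sample).
#' @param sessions Session order; defaults to sorted unique sessions.
#' @return List of `S` folds, each `list(session, train, test)` with integer
#'   row indices.
#' @export
loso_split <- function(meta, sessions = NULL) {
  if (is.null(sessions)) sessions <- sort(unique(meta$session))
  if (length(sessions) < 2L) {
    stop_gazeid("LOSO needs at least 2 sessions", "gazeid_validation_error")
  }
  lapply(sessions, function(s) {
    test <- which(meta$session == s)
    list(session = s, train = which(meta$session != s), test = test)
  })
}

#' Fuse per-sample probability vectors into a user-level vector
#'
#' Score-level fusion: the identity probability vector of a user is the
#' arithmetic mean of the probability vectors of all the user's test samples
#' (`X` positions times `G` segments). The mean of normalised vectors is
#' itself normalised.
#'
#' @param p Matrix `[m, l]` of per-sample probability vectors (rows sum
#'   to 1), or a single vector.
#' @return Numeric vector of length `l` summing to 1.
#' @export
fuse_probabilities <- function(p) {
  if (is.vector(p)) p <- matrix(p, nrow = 1)
  if (nrow(p) == 0L) {
    stop_gazeid("cannot fuse an empty set of probability vectors",
                "gazeid_validation_error")
  }
  if (any(abs(rowSums(p) - 1) > 1e-6) || any(p < -1e-12)) {
    stop_gazeid("rows must be probability vectors summing to 1",
                "gazeid_validation_error")
  }
  colMeans(p)
}

#' Identity decision from a fused probability vector
#'
#' Argmax over classes; ties break toward the lowest class index (a
#' documented, deterministic rule -- exact ties are measure-zero in practice).
#'
#' @param p_ui Fused probability vector.
#' @return Integer class index.
#' @export
decide_label <- function(p_ui) {
  which.max(p_ui)
}

#' Multiclass identification metrics
#'
#' Accuracy, macro-averaged F1 (unweighted mean of per-class F1, with 0 for
#' classes whose precision and recall are both undefined) and Cohen's kappa
#' computed from the confusion-matrix marginals.
#'
#' @param pred,truth Equal-length integer label vectors.
#' @param l Number of classes.
#' @return Named numeric vector `accuracy`, `f1`, `kappa`.
#' @export
compute_metrics <- function(pred, truth, l) {
  if (length(pred) == 0L || length(pred) != length(truth)) {
    stop_gazeid("pred and truth must be non-empty and of equal length",
                "gazeid_validation_error")
  }
  n <- length(pred)
  cm <- table(factor(pred, levels = seq_len(l)),
              factor(truth, levels = seq_len(l)))
  acc <- sum(diag(cm)) / n
  f1s <- vapply(seq_len(l), function(k) {
    tp <- cm[k, k]
    prec_den <- sum(cm[k, ])
    rec_den <- sum(cm[, k])
    prec <- if (prec_den > 0) tp / prec_den else 0
    rec <- if (rec_den > 0) tp / rec_den else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  f1 <- mean(f1s)
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (abs(1 - pe) < 1e-15) NaN else (acc - pe) / (1 - pe)
  c(accuracy = acc, f1 = f1, kappa = kappa)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Run the full LOSO identification experiment
#'
#' For each fold: min-max scalers are fitted on the training sessions and
#' applied (with clipping) to the held-out session; a fresh classifier is
#' trained; per-sample probabilities on the held-out session are fused per
#' user by arithmetic mean and the identity decided by argmax; accuracy,
#' macro F1 and Cohen's kappa are computed over the fused user-level
#' decisions. The report aggregates metrics as mean and population standard
#' deviation over folds.
#'
#' @param features A [build_feature_dataset()] result.
#' @param spec A [model_spec()] (`kind` selects the feature representation:
#'   `"lstm"` consumes the time-series channels, `"dense"` the 16 statistical
#'   values derived from them).
#' @param cfg A [train_config()]; each fold trains with seed
#'   `cfg$seed + fold`.
#' @param scale_mode `"train"` fits scaler extrema on the training sessions
#'   only (no test leakage); `"global"` fits them on all sessions.
#' @param per_sample Also record sample-level (pre-fusion) metrics per fold.
#' @return An object of class `evaluation_report`: per-fold results and a
#'   `summary` data frame of mean/sd per metric.
#' @export
run_experiment <- function(features, spec, cfg = train_config(),
                           scale_mode = c("train", "global"),
                           per_sample = FALSE) {
  stopifnot(inherits(features, "gaze_features"), inherits(spec, "model_spec"))
  scale_mode <- match.arg(scale_mode)
  meta <- features$meta
  subjects <- sort(unique(meta$subject))
  if (length(subjects) != spec$num_labels) {
    stop_gazeid(sprintf("design mismatch: %d subjects in data, %d labels in spec",
                        length(subjects), spec$num_labels),
                "gazeid_validation_error")
  }
  labels <- match(meta$subject, subjects)
  folds <- loso_split(meta)
  fold_results <- vector("list", length(folds))
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    scalers <- fit_scalers(features$ts,
                           if (scale_mode == "train") fold$train
                           else seq_len(dim(features$ts)[1]))
    scaled <- apply_scalers(features$ts, scalers)
    if (spec$kind == "lstm") {
      x_train <- scaled[fold$train, , , drop = FALSE]
      x_test <- scaled[fold$test, , , drop = FALSE]
    } else {
      stats_all <- stat_matrix(scaled)
      x_train <- stats_all[fold$train, , drop = FALSE]
      x_test <- stats_all[fold$test, , drop = FALSE]
    }
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + fi
    model <- build_model(spec, seed = fold_cfg$seed)
    model <- train_model(model, x_train, labels[fold$train], fold_cfg)
    probs <- predict_proba(model, x_test)
    test_labels <- labels[fold$test]
    test_subjects <- meta$subject[fold$test]
    fused <- t(vapply(subjects, function(s) {
      fuse_probabilities(probs[test_subjects == s, , drop = FALSE])
    }, numeric(spec$num_labels)))
    decisions <- apply(fused, 1, decide_label)
    truth <- match(subjects, subjects)
    metrics <- compute_metrics(decisions, truth, spec$num_labels)
    res <- list(session = fold$session, fused = fused, decisions = decisions,
                metrics = metrics, loss_trace = model$loss_trace)
    if (per_sample) {
      sample_pred <- apply(probs, 1, which.max)
      res$sample_metrics <- compute_metrics(sample_pred, test_labels,
                                            spec$num_labels)
    }
    fold_results[[fi]] <- res
  }
  metric_mat <- do.call(rbind, lapply(fold_results, `[[`, "metrics"))
  summary <- data.frame(metric = colnames(metric_mat),
                        mean = colMeans(metric_mat),
                        sd = apply(metric_mat, 2, pop_sd),
                        row.names = NULL)
  structure(list(folds = fold_results, summary = summary,
                 subjects = subjects, spec = spec,
                 scale_mode = scale_mode),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s model, %d users, %d LOSO folds\n",
              x$spec$kind, length(x$subjects), length(x$folds)))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-9s %.3f (%.3f)\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  }
  invisible(x)
}

#' Write an evaluation report to JSON and CSV
#'
#' @param report An [run_experiment()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, prefix = "report") {
  stopifnot(inherits(report, "evaluation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  per_fold <- do.call(rbind, lapply(report$folds, function(f) {
    data.frame(session = f$session, t(f$metrics))
  }))
  csv_path <- file.path(dir, paste0(prefix, ".csv"))
  utils::write.csv(rbind(per_fold,
                         data.frame(session = "mean",
                                    t(colMeans(as.matrix(per_fold[, -1]))))),
                   csv_path, row.names = FALSE)
  json_path <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(list(model = report$spec$kind,
                            subjects = report$subjects,
                            scale_mode = report$scale_mode,
                            per_fold = per_fold,
                            summary = report$summary),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, json = json_path))
}
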