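#' Assemble an ROI feature dataset for classification
#'
#' Validates and packages a feature table for [train_ensemble()]: every row
#' is one ROI with its milestone features, a `benign`/`cancer` label and a
#' patient id (used to keep all of a patient's ROIs in one
#' cross-validation fold).
#'
#' @param features `data.frame` containing the feature columns plus
#'   `label` and `patient_id` (and optionally `roi_id`).
#' @param feature_cols Feature column names (default: the five milestones
#'   and their lesion-minus-normal deltas, intersected with what is
#'   present).
#' @return An `roi_dataset` object.
#' @export
roi_dataset <- function(features, feature_cols = NULL) {
  assert_that(is.data.frame(features), "`features` must be a data.frame")
  assert_that(all(c("label", "patient_id") %in% names(features)),
              "`features` needs `label` and `patient_id` columns")
  if (is.null(feature_cols))
    feature_cols <- intersect(feature_columns(), names(features))
  assert_that(length(feature_cols) >= 1L, "no feature columns found")
  missing <- setdiff(feature_cols, names(features))
  assert_that(length(missing) == 0L, "missing feature columns: %s",
              paste(missing, collapse = ", "))
  X <- as.matrix(features[, feature_cols, drop = FALSE])
  assert_that(is.numeric(X) && !anyNA(X),
              "feature columns must be numeric with no missing values")
  assert_that(all(features$label %in% c("benign", "cancer")),
              "labels must be benign/cancer")
  structure(list(
    X = X, labels = features$label,
    patient_id = as.character(features$patient_id),
    roi_id = as.character(features$roi_id %||% seq_len(nrow(X))),
    feature_cols = feature_cols,
    class_balance = table(features$label)),
    class = "roi_dataset")
}

#' Hyperparameter search space for the tree ensembles
#'
#' The default grid spans bagged trees (`trees` x `depth`) and gradient
#' boosted trees (`trees` x `depth` x `learning_rate`), mirroring the
#' "optimizable ensemble" idea of a seeded search over tree-ensemble
#' families.
#'
#' @param trees Candidate ensemble sizes.
#' @param depth Candidate maximum tree depths.
#' @param learning_rate Candidate learning rates (boosted family only).
#' @param families Which families to include.
#' @return List of candidate configurations.
#' @export
ensemble_search_space <- function(trees = c(50L, 100L, 200L),
                                  depth = c(2L, 4L, 8L),
                                  learning_rate = c(0.05, 0.1, 0.3),
                                  families = c("bag", "boost")) {
  out <- list()
  if ("bag" %in% families)
    for (nt in trees) for (d in depth)
      out[[length(out) + 1L]] <- list(family = "bag", trees = nt, depth = d)
  if ("boost" %in% families)
    for (nt in trees) for (d in depth) for (lr in learning_rate)
      out[[length(out) + 1L]] <- list(family = "boost", trees = nt,
                                      depth = d, learning_rate = lr)
  out
}

# assign patients (not rows) to folds: seeded shuffle, round-robin
patient_folds <- function(patient_id, folds, seed) {
  patients <- unique(patient_id)
  assert_that(length(patients) >= folds,
              "fewer patients (%d) than folds (%d)",
              length(patients), folds)
  shuffled <- with_seed(seed, sample(patients))
  fold_of <- stats::setNames(rep_len(seq_len(folds), length(shuffled)),
                             shuffled)
  unname(fold_of[patient_id])
}

fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd <= 0] <- 1
  list(center = mu, scale = sd)
}

apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
}

fit_config <- function(cfg, X, y, seed) {
  if (cfg$family == "bag")
    fit_bagged(X, y, n_trees = cfg$trees, max_depth = cfg$depth, seed = seed)
  else
    fit_boosted(X, y, n_trees = cfg$trees, max_depth = cfg$depth,
                learning_rate = cfg$learning_rate, seed = seed)
}

#' Train the ensemble classifier with patient-grouped cross-validation
#'
#' Scores every candidate configuration by mean accuracy over
#' patient-grouped k-fold cross-validation (no patient's ROIs span folds;
#' per-feature standardization is refit on each training fold), then
#' refits the best configuration on the full dataset.
#'
#' @param dataset An [roi_dataset()] with at least two classes.
#' @param folds Number of cross-validation folds (default 5).
#' @param search_space Candidate configurations, see
#'   [ensemble_search_space()].
#' @param seed RNG seed (fold assignment and bootstrap resampling).
#' @return An `ensemble_model` with the fitted ensemble, scaler, seed and a
#'   CV report (`cv_report$grid`, per-fold accuracies of the winner).
#' @export
train_ensemble <- function(dataset, folds = 5L,
                           search_space = ensemble_search_space(),
                           seed = 1L) {
  assert_that(inherits(dataset, "roi_dataset"),
              "`dataset` must be an roi_dataset")
  classes <- sort(unique(dataset$labels))
  assert_that(length(classes) >= 2L,
              "single-class dataset: need both benign and cancer ROIs")
  y <- as.numeric(dataset$labels == "cancer")
  fold_id <- patient_folds(dataset$patient_id, folds,
                           derive_seed(seed, "folds"))

  grid <- data.frame(config = seq_along(search_space),
                     family = vapply(search_space, `[[`, "", "family"),
                     trees = vapply(search_space, `[[`, 0L, "trees"),
                     depth = vapply(search_space, `[[`, 0L, "depth"),
                     learning_rate = vapply(search_space, function(cfg)
                       cfg$learning_rate %||% NA_real_, 0),
                     mean_cv_accuracy = NA_real_)
  fold_acc <- matrix(NA_real_, length(search_space), folds)
  for (ci in seq_along(search_space)) {
    cfg <- search_space[[ci]]
    for (k in seq_len(folds)) {
      tr <- fold_id != k; te <- !tr
      scaler <- fit_scaler(dataset$X[tr, , drop = FALSE])
      Xtr <- apply_scaler(scaler, dataset$X[tr, , drop = FALSE])
      Xte <- apply_scaler(scaler, dataset$X[te, , drop = FALSE])
      fit <- fit_config(cfg, Xtr, y[tr],
                        derive_seed(seed, sprintf("cfg%d_fold%d", ci, k)))
      pred <- predict_fit(fit, Xte) >= 0.5
      fold_acc[ci, k] <- mean(pred == (y[te] == 1))
    }
  }
  grid$mean_cv_accuracy <- rowMeans(fold_acc)
  best <- which.max(grid$mean_cv_accuracy)
  scaler <- fit_scaler(dataset$X)
  fit <- fit_config(search_space[[best]],
                    apply_scaler(scaler, dataset$X), y,
                    derive_seed(seed, "final"))
  structure(list(
    fit = fit, config = search_space[[best]], scaler = scaler,
    feature_cols = dataset$feature_cols, classes = c("benign", "cancer"),
    seed = seed, folds = folds,
    cv_report = list(grid = grid,
                     best_config = best,
                     fold_accuracy = fold_acc[best, ],
                     mean_cv_accuracy = grid$mean_cv_accuracy[best])),
    class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "ensemble_model: %s, %d trees, depth %d%s\n", cfg$family, cfg$trees,
    cfg$depth,
    if (cfg$family == "boost") sprintf(", lr %g", cfg$learning_rate) else ""))
  cat(sprintf("  mean %d-fold CV accuracy: %.3f\n", x$folds,
              x$cv_report$mean_cv_accuracy))
  invisible(x)
}

#' Predict ROI class probabilities
#'
#' @param model An `ensemble_model` from [train_ensemble()].
#' @param features `data.frame` (or matrix) holding the model's feature
#'   columns; extra columns are ignored, missing ones are a schema error.
#' @param threshold Probability cut for the hard call (default 0.5).
#' @return `data.frame` with `probability` (of cancer) and `call`.
#' @export
predict_roi <- function(model, features, threshold = 0.5) {
  assert_that(inherits(model, "ensemble_model"),
              "`model` must be an ensemble_model")
  if (inherits(features, "roi_dataset")) {
    X <- features$X[, , drop = FALSE]
    cols <- features$feature_cols
  } else {
    features <- as.data.frame(features)
    cols <- names(features)
    missing <- setdiff(model$feature_cols, cols)
    assert_that(length(missing) == 0L,
                "feature schema mismatch: missing column(s) %s",
                paste(missing, collapse = ", "))
    X <- as.matrix(features[, model$feature_cols, drop = FALSE])
  }
  if (!identical(colnames(X), model$feature_cols)) {
    missing <- setdiff(model$feature_cols, colnames(X))
    assert_that(length(missing) == 0L,
                "feature schema mismatch: missing column(s) %s",
                paste(missing, collapse = ", "))
    X <- X[, model$feature_cols, drop = FALSE]
  }
  p <- predict_fit(model$fit, apply_scaler(model$scaler, X))
  data.frame(probability = p,
             call = ifelse(p >= threshold, "cancer", "benign"),
             stringsAsFactors = FALSE)
}

#' Aggregate ROI calls to one patient-level call
#'
#' @param calls Character vector of per-ROI calls (`benign`/`cancer`) for
#'   one patient's lesion ROIs.
#' @param rule `"any"` (default; any cancer ROI makes the patient a cancer
#'   call) or `"majority"` (modal call, ties resolved to cancer).
#' @return `"benign"` or `"cancer"`.
#' @export
aggregate_patient <- function(calls, rule = c("any", "majority")) {
  rule <- match.arg(rule)
  assert_that(length(calls) >= 1L, "no ROI calls to aggregate")
  assert_that(all(calls %in% c("benign", "cancer")),
              "calls must be benign/cancer")
  if (rule == "any") {
    if (any(calls == "cancer")) "cancer" else "benign"
  } else {
    n_cancer <- sum(calls == "cancer")
    if (n_cancer * 2 >= length(calls)) "cancer" else "benign"
  }
}

#' Confusion matrix and diagnostic metrics
#'
#' Compares predicted calls with truth at any unit level (ROI or patient),
#' with cancer as the positive class. Percentages are reported both raw
#' and rounded to the nearest integer (half away from zero), the precision
#' clinical report tables use.
#'
#' @param calls,truth Character vectors (`benign`/`cancer`). When both are
#'   named, units are aligned by name and a mismatch is an error.
#' @return A `prediction_metrics` list: `tp`, `fp`, `tn`, `fn`, `accuracy`,
#'   `sensitivity`, `specificity` (raw, in %), and a `rounded` sub-list.
#' @examples
#' # patient-level confusion with 7 TP / 0 FN / 5 TN / 2 FP -> 86% accuracy
#' ev <- evaluate_calls(rep(c("cancer", "cancer", "benign"), c(9, 0, 5)),
#'                      rep(c("cancer", "benign", "benign"), c(7, 2, 5)))
#' ev$rounded$accuracy
#' @export
evaluate_calls <- function(calls, truth) {
  if (!is.null(names(calls)) && !is.null(names(truth))) {
    assert_that(setequal(names(calls), names(truth)),
                "unit ids of `calls` and `truth` differ")
    truth <- truth[names(calls)]
  }
  assert_that(length(calls) == length(truth),
              "`calls` (%d) and `truth` (%d) lengths differ",
              length(calls), length(truth))
  assert_that(all(c(calls, truth) %in% c("benign", "cancer")),
              "calls and truth must be benign/cancer")
  tp <- sum(calls == "cancer" & truth == "cancer")
  fp <- sum(calls == "cancer" & truth == "benign")
  tn <- sum(calls == "benign" & truth == "benign")
  fn <- sum(calls == "benign" & truth == "cancer")
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  acc <- pct(tp + tn, length(calls))
  sens <- pct(tp, tp + fn)
  spec <- pct(tn, tn + fp)
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn, n = length(calls),
    accuracy = acc, sensitivity = sens, specificity = spec,
    rounded = list(accuracy = round_half_up(acc),
                   sensitivity = round_half_up(sens),
                   specificity = round_half_up(spec))),
    class = "prediction_metrics")
}

#' @export
print.prediction_metrics <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$n))
  cat(sprintf("accuracy %g%%, sensitivity %g%%, specificity %g%%\n",
              x$rounded$accuracy, x$rounded$sensitivity,
              x$rounded$specificity))
  invisible(x)
}
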