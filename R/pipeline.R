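#' Pipeline configuration
#'
#' One validated configuration object drives the whole desk-scale
#' pipeline: simulate a dual-channel recording and rater table, track the
#' ROIs, extract milestone features, train/apply the ensemble classifier
#' on a simulated ROI dataset, and run the rater statistics. The global
#' `seed` fans out deterministically to per-stage seeds (stage-name hash),
#' so each stage is independently re-runnable.
#'
#' @param out_dir Output directory.
#' @param scene A [scene_spec()].
#' @param rater A [rater_model_params()].
#' @param dataset List of [simulate_roi_dataset()] arguments for the
#'   classifier training set.
#' @param track A [track_config()].
#' @param features A [feature_config()].
#' @param folds CV folds for [train_ensemble()].
#' @param search_space Classifier search space
#'   ([ensemble_search_space()]).
#' @param aggregate_rule ROI-to-patient rule (`"any"`/`"majority"`).
#' @param seed Global seed.
#' @param log_level `"info"` or `"quiet"`.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            scene = scene_spec(),
                            rater = rater_model_params(),
                            dataset = list(n_patients = 16,
                                           rois_per_patient = 4),
                            track = track_config(),
                            features = feature_config(),
                            folds = 5L,
                            search_space = ensemble_search_space(
                              trees = 100L, depth = c(2L, 4L)),
                            aggregate_rule = "any",
                            seed = 1L,
                            log_level = "info") {
  assert_that(is.character(out_dir) && length(out_dir) == 1L,
              "`out_dir` must be a directory path")
  assert_that(inherits(scene, "scene_spec"), "`scene` must be a scene_spec")
  assert_that(inherits(rater, "rater_model_params"),
              "`rater` must be rater_model_params")
  assert_that(inherits(track, "track_config"),
              "`track` must be a track_config")
  assert_that(inherits(features, "feature_config"),
              "`features` must be a feature_config")
  assert_that(aggregate_rule %in% c("any", "majority"),
              "`aggregate_rule` must be 'any' or 'majority'")
  assert_number(folds, "folds", lower = 2)
  structure(list(out_dir = out_dir, scene = scene, rater = rater,
                 dataset = dataset, track = track, features = features,
                 folds = as.integer(folds), search_space = search_space,
                 aggregate_rule = aggregate_rule,
                 seed = as.integer(seed), log_level = log_level),
            class = "pipeline_config")
}

pipe_log <- function(config, fmt, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf(paste0("[fluoroperf] ", fmt), ...))
}

#' Run the full pipeline
#'
#' Executes simulate, track, features, train, classify and raterstats in
#' dependency order, skipping stages whose outputs already exist unless
#' `force = TRUE`, and writes a consolidated `report.json` (timestamps are
#' deliberately excluded so repeated runs are byte-identical).
#'
#' @param config A [pipeline_config()].
#' @param force Re-run stages whose outputs exist.
#' @return The consolidated report list, invisibly.
#' @export
run_pipeline <- function(config, force = FALSE) {
  assert_that(inherits(config, "pipeline_config"),
              "`config` must be a pipeline_config")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  bundle_dir <- file.path(out, "bundle")
  curves_csv <- file.path(out, "curves.csv")
  features_csv <- file.path(out, "features.csv")
  model_json <- file.path(out, "model.json")
  preds_csv <- file.path(out, "preds.csv")
  stats_dir <- file.path(out, "raterstats")

  run_stage <- function(name, outputs, fun) {
    if (!force && all(file.exists(outputs))) {
      pipe_log(config, "stage %s: outputs exist, skipping", name)
      return(invisible())
    }
    pipe_log(config, "stage %s: running (seed %d)", name,
             derive_seed(config$seed, name))
    tryCatch(fun(), error = function(e)
      stop_fp("stage %s failed: %s", name, conditionMessage(e)))
  }

  # 1. simulate ---------------------------------------------------------
  scene <- config$scene
  scene$seed <- derive_seed(config$seed, "simulate")
  rater <- config$rater
  rater$seed <- derive_seed(config$seed, "rater")
  run_stage("simulate", file.path(bundle_dir, "manifest.yaml"), function()
    write_fixture_bundle(bundle_dir, scene, rater))

  # 2. track ------------------------------------------------------------
  run_stage("track", curves_csv, function() {
    bundle <- read_fixture_bundle(bundle_dir)
    curves <- lapply(bundle$rois, function(roi) {
      trk <- track_roi(bundle$white, roi, config$track)
      extract_curve(bundle$nir, trk, roi, fps = bundle$scene$fps)
    })
    write_curves_csv(curves, curves_csv)
  })

  # 3. features ---------------------------------------------------------
  run_stage("features", features_csv, function() {
    curves <- read_curves_csv(curves_csv)
    feats <- curves_to_features(curves, config$features,
                                patient_id = "sim01")
    write_features_csv(feats, features_csv)
  })

  # 4. train ------------------------------------------------------------
  run_stage("train", model_json, function() {
    args <- config$dataset
    args$seed <- derive_seed(config$seed, "train_data")
    ds <- roi_dataset(do.call(simulate_roi_dataset, args))
    model <- train_ensemble(ds, folds = config$folds,
                            search_space = config$search_space,
                            seed = derive_seed(config$seed, "train"))
    save_model(model, model_json)
  })

  # 5. classify ---------------------------------------------------------
  run_stage("classify", preds_csv, function() {
    model <- load_model(model_json)
    feats <- read_features_csv(features_csv)
    lesions <- feats[feats$label != "normal", , drop = FALSE]
    assert_that(nrow(lesions) >= 1L, "no lesion ROIs to classify")
    pred <- predict_roi(model, lesions)
    roi_rows <- data.frame(unit_id = lesions$roi_id, level = "roi",
                           probability = pred$probability,
                           call = pred$call,
                           truth = ifelse(lesions$label == "malignant",
                                          "cancer", "benign"),
                           stringsAsFactors = FALSE)
    pat_call <- aggregate_patient(pred$call, config$aggregate_rule)
    pat_truth <- if (any(roi_rows$truth == "cancer")) "cancer" else "benign"
    pat_rows <- data.frame(unit_id = lesions$patient_id[1],
                           level = "patient", probability = NA_real_,
                           call = pat_call, truth = pat_truth,
                           stringsAsFactors = FALSE)
    utils::write.csv(rbind(roi_rows, pat_rows), preds_csv,
                     row.names = FALSE)
  })

  # 6. raterstats -------------------------------------------------------
  run_stage("raterstats", file.path(stats_dir, "report.json"), function() {
    bundle <- read_fixture_bundle(bundle_dir)
    tab <- bundle$rater_table
    rater_stats_report(tab, truth = data.frame(
      polyp_id = bundle$truth$polyp_id,
      pathology = bundle$truth$pathology), out_dir = stats_dir)
  })

  # consolidated report -------------------------------------------------
  report <- build_report(config, curves_csv, features_csv, model_json,
                         preds_csv, stats_dir)
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = 10, force = TRUE,
                       dataframe = "rows")
  pipe_log(config, "report written to %s", file.path(out, "report.json"))
  invisible(report)
}

# milestone features for every curve, deltas vs the normal-tissue
# reference (first normal ROI)
curves_to_features <- function(curves, config = feature_config(),
                               patient_id = "sim01",
                               reference_label = "normal") {
  feats <- lapply(curves, function(cv)
    extract_milestones(preprocess_curve(cv, config), config,
                       recording_id = patient_id))
  labels <- vapply(feats, `[[`, "", "label")
  ref_idx <- which(labels == reference_label)[1]
  rows <- lapply(feats, function(f) {
    if (!is.na(ref_idx)) f <- relative_features(f, feats[[ref_idx]])
    cols <- intersect(feature_columns(), names(f))
    data.frame(roi_id = f$roi_id, label = f$label, patient_id = patient_id,
               as.data.frame(unclass(f)[cols]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

build_report <- function(config, curves_csv, features_csv, model_json,
                         preds_csv, stats_dir) {
  feats <- read_features_csv(features_csv)
  model <- load_model(model_json)
  preds <- utils::read.csv(preds_csv, stringsAsFactors = FALSE)
  rater_report <- jsonlite::read_json(file.path(stats_dir, "report.json"),
                                      simplifyVector = TRUE)
  roi_pred <- preds[preds$level == "roi", ]
  milestone_summary <- lapply(split(feats, feats$label), function(g)
    lapply(as.list(g[, intersect(milestone_names(), names(g))]), mean))
  list(
    config = list(seed = config$seed,
                  fps = config$scene$fps,
                  duration_s = config$scene$duration,
                  icg_dose_mg_kg = config$scene$icg_dose_mg_kg,
                  aggregate_rule = config$aggregate_rule),
    simulation = list(n_frames = config$scene$n_frames,
                      regions = length(config$scene$regions)),
    tracking = list(n_curves = length(unique(feats$roi_id))),
    milestones = milestone_summary,
    classifier = list(
      family = model$config$family,
      config = model$config,
      mean_cv_accuracy = model$cv_report$mean_cv_accuracy,
      fold_accuracy = model$cv_report$fold_accuracy,
      confusion = unclass(evaluate_calls(roi_pred$call, roi_pred$truth)),
      patient_call = preds$call[preds$level == "patient"]),
    rater_stats = rater_report)
}
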