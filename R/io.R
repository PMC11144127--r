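# Readers and writers for the pipeline's on-disk formats. Every reader
# validates its schema and names the offending file/column on error;
# writers round-trip bit-exactly for integer payloads and to float
# precision for numeric ones.

read_csv_checked <- function(path, required, what) {
  assert_that(file.exists(path), "%s file not found: %s", what, path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  assert_that(length(missing) == 0L,
              "%s file %s: missing column(s) %s", what, path,
              paste(missing, collapse = ", "))
  df
}

#' Write / read ROI specifications as JSON
#'
#' Format: a JSON array of `{id, label, bbox: [r0, c0, r1, c1]}` objects,
#' boxes half-open in 0-based frame-0 coordinates.
#'
#' @param rois List of [roi_spec()] objects.
#' @param path File path.
#' @return `write_roi_json`: `path` invisibly; `read_roi_json`: list of
#'   [roi_spec()].
#' @export
write_roi_json <- function(rois, path) {
  payload <- lapply(rois, function(r)
    list(id = r$id, label = r$label, bbox = as.integer(r$bbox)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  assert_that(file.exists(path), "ROI file not found: %s", path)
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(r) {
    assert_that(!is.null(r$id) && !is.null(r$bbox),
                "ROI record in %s missing id/bbox", path)
    roi_spec(id = r$id, label = r$label %||% "unknown",
             bbox = unlist(r$bbox))
  })
}

#' Write / read time-intensity curves as CSV
#'
#' Schema: `roi_id, label, frame, time_s, intensity, valid` (frame 0-based).
#'
#' @param curves List of [time_intensity_curve()] objects.
#' @param path File path.
#' @return `write_curves_csv`: `path` invisibly; `read_curves_csv`: list
#'   of curves.
#' @export
write_curves_csv <- function(curves, path) {
  if (inherits(curves, "time_intensity_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(roi_id = cv$roi_id, label = cv$label,
               frame = seq_along(cv$times) - 1L,
               time_s = cv$times, intensity = cv$intensities,
               valid = cv$valid, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves_csv
#' @export
read_curves_csv <- function(path) {
  df <- read_csv_checked(path, c("roi_id", "label", "frame", "time_s",
                                 "intensity", "valid"), "curves")
  lapply(split(df, factor(df$roi_id, levels = unique(df$roi_id))),
         function(sub) {
           sub <- sub[order(sub$frame), ]
           fps <- if (nrow(sub) > 1)
             1 / (sub$time_s[2] - sub$time_s[1]) else 30
           time_intensity_curve(sub$roi_id[1], sub$label[1], sub$time_s,
                                sub$intensity, round(fps, 6),
                                valid = as.logical(sub$valid))
         })
}

#' Write / read milestone feature tables as CSV
#'
#' Schema: `roi_id, label, patient_id` plus the five milestones and their
#' `d_`-prefixed deltas.
#'
#' @param features `data.frame` of features.
#' @param path File path.
#' @return The table (readers) or `path` invisibly (writers).
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  read_csv_checked(path, c("roi_id", "label", "patient_id",
                           milestone_names()), "features")
}

#' Write / read rater-response tables as CSV
#'
#' Schema: `rater_id, grade, polyp_id, answer, confidence` (long format);
#' the companion truth file is `polyp_id, pathology, size_mm`.
#'
#' @param table Long rater table.
#' @param path File path.
#' @return The table (readers) or `path` invisibly (writers).
#' @export
write_rater_csv <- function(table, path) {
  cols <- intersect(c("rater_id", "grade", "polyp_id", "answer",
                      "confidence"), names(table))
  utils::write.csv(table[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rater_csv
#' @export
read_rater_csv <- function(path) {
  df <- read_csv_checked(path, c("rater_id", "polyp_id", "answer",
                                 "confidence"), "rater")
  assert_that(all(df$answer %in% c("benign", "cancer")),
              "rater file %s: answers must be benign/cancer", path)
  assert_that(all(df$confidence %in% 1:5),
              "rater file %s: confidence must be 1..5", path)
  df
}

#' @rdname write_rater_csv
#' @param truth Truth table (`polyp_id, pathology, size_mm`).
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth[, c("polyp_id", "pathology", "size_mm")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_rater_csv
#' @export
read_truth_csv <- function(path) {
  df <- read_csv_checked(path, c("polyp_id", "pathology"), "truth")
  assert_that(all(df$pathology %in% c("benign", "cancer")),
              "truth file %s: pathology must be benign/cancer", path)
  df
}

#' Save / load a trained ensemble model
#'
#' The model (trees, hyperparameters, standardization constants, feature
#' schema, seed and CV report) is stored as a single self-describing JSON
#' archive via [jsonlite::serializeJSON()], which round-trips the R object
#' exactly.
#'
#' @param model An `ensemble_model`.
#' @param path File path (conventionally `.json`).
#' @return `save_model`: `path` invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  assert_that(inherits(model, "ensemble_model"),
              "`model` must be an ensemble_model")
  writeLines(jsonlite::serializeJSON(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  assert_that(file.exists(path), "model file not found: %s", path)
  model <- jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
  assert_that(inherits(model, "ensemble_model"),
              "%s does not contain an ensemble_model", path)
  model
}

# scene_spec <-> plain-list manifest form ------------------------------

scene_to_manifest <- function(scene) {
  list(frame_size = as.integer(scene$frame_size),
       duration = scene$duration, fps = scene$fps,
       regions = lapply(scene$regions, function(r)
         list(id = r$id, label = r$label, bbox = as.integer(r$bbox))),
       kinetics = lapply(scene$kinetics, unclass),
       jitter = apply(scene$jitter, 1, as.integer, simplify = FALSE),
       nir_background = scene$nir_background,
       white_noise_sd = scene$white_noise_sd,
       texture_seed = scene$texture_seed, seed = scene$seed,
       icg_dose_mg_kg = scene$icg_dose_mg_kg)
}

scene_from_manifest <- function(m) {
  jit <- do.call(rbind, lapply(m$jitter, unlist))
  scene_spec(frame_size = unlist(m$frame_size), duration = m$duration,
             fps = m$fps,
             regions = lapply(m$regions, function(r)
               list(id = r$id, label = r$label, bbox = unlist(r$bbox))),
             kinetics = lapply(m$kinetics, function(k)
               do.call(kinetic_params, k)),
             jitter = jit, nir_background = m$nir_background,
             white_noise_sd = m$white_noise_sd,
             texture_seed = m$texture_seed, seed = m$seed,
             icg_dose_mg_kg = m$icg_dose_mg_kg)
}

rater_params_to_manifest <- function(p) unclass(p)

rater_params_from_manifest <- function(m) {
  rater_model_params(n_raters = m$n_raters, n_items = m$n_items,
                     difficulty = unlist(m$difficulty),
                     skill = unlist(m$skill), truth = unlist(m$truth),
                     grades = unlist(m$grades),
                     confidence_breaks = unlist(m$confidence_breaks),
                     confidence_noise_sd = m$confidence_noise_sd,
                     seed = m$seed)
}

#' Write a self-describing synthetic fixture bundle
#'
#' Renders a [scene_spec()] and simulates a rater table, writing the full
#' interchange bundle: white/NIR TIFF stacks (`_wl.tif` / `_nir.tif`),
#' 8-bit label mask TIFF, ROI JSON, rater CSV, truth CSV, the ground-truth
#' displacement/curve CSVs, and a YAML manifest holding every parameter
#' and seed so the bundle round-trips through the readers.
#'
#' @param path Output directory (created if needed).
#' @param scene A [scene_spec()].
#' @param rater_params A [rater_model_params()].
#' @param prefix Filename prefix for the channel stacks.
#' @return Invisibly, the list of written paths.
#' @export
write_fixture_bundle <- function(path, scene = scene_spec(),
                                 rater_params = rater_model_params(),
                                 prefix = "video") {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  rendered <- render_video_pair(scene)
  p <- function(...) file.path(path, paste0(...))
  paths <- list(
    wl = p(prefix, "_wl.tif"), nir = p(prefix, "_nir.tif"),
    mask = p(prefix, "_mask.tif"), rois = p("rois.json"),
    rater = p("rater.csv"), truth = p("truth.csv"),
    displacement = p("displacement.csv"), curves = p("true_curves.csv"),
    manifest = p("manifest.yaml"))
  write_tiff_stack(rendered$white, paths$wl, bits = 16)
  write_tiff_stack(rendered$nir, paths$nir, bits = 16)
  write_tiff_stack(rendered$mask, paths$mask, bits = 8)
  rois <- lapply(scene$regions, function(r)
    roi_spec(r$id, r$label, r$bbox))
  write_roi_json(rois, paths$rois)
  rater_tab <- simulate_rater_table(rater_params)
  write_rater_csv(rater_tab, paths$rater)
  sizes <- with_seed(derive_seed(rater_params$seed, "sizes"),
                     round(pmin(pmax(stats::rnorm(rater_params$n_items,
                                                  44, 25), 10), 130)))
  write_truth_csv(data.frame(polyp_id = seq_len(rater_params$n_items),
                             pathology = rater_params$truth,
                             size_mm = sizes), paths$truth)
  utils::write.csv(data.frame(frame = seq_len(scene$n_frames) - 1L,
                              d_row = rendered$displacement[, 1],
                              d_col = rendered$displacement[, 2]),
                   paths$displacement, row.names = FALSE)
  true_curves <- mapply(function(id, y) {
    r <- scene$regions[[which(rendered$region_ids == id)]]
    time_intensity_curve(id, r$label, rendered$times, y, scene$fps)
  }, rendered$region_ids, rendered$curves, SIMPLIFY = FALSE)
  write_curves_csv(true_curves, paths$curves)
  manifest <- list(format = "fluoroperf-bundle-v1",
                   prefix = prefix,
                   n_frames = scene$n_frames,
                   scene = scene_to_manifest(scene),
                   rater = rater_params_to_manifest(rater_params))
  yaml::write_yaml(manifest, paths$manifest)
  invisible(paths)
}

#' Read back a fixture bundle
#'
#' @param path Bundle directory written by [write_fixture_bundle()].
#' @return List with `scene`, `rater_params`, `white`, `nir`, `mask`,
#'   `rois`, `rater_table`, `truth`, `displacement`, `true_curves`,
#'   `manifest`.
#' @export
read_fixture_bundle <- function(path) {
  mp <- file.path(path, "manifest.yaml")
  assert_that(file.exists(mp), "bundle manifest not found: %s", mp)
  manifest <- yaml::read_yaml(mp)
  assert_that(identical(manifest$format, "fluoroperf-bundle-v1"),
              "%s: unknown bundle format", mp)
  prefix <- manifest$prefix
  p <- function(...) file.path(path, paste0(...))
  disp <- read_csv_checked(p("displacement.csv"),
                           c("frame", "d_row", "d_col"), "displacement")
  list(scene = scene_from_manifest(manifest$scene),
       rater_params = rater_params_from_manifest(manifest$rater),
       white = read_tiff_stack(p(prefix, "_wl.tif")),
       nir = read_tiff_stack(p(prefix, "_nir.tif")),
       mask = read_tiff_stack(p(prefix, "_mask.tif"))[, , 1],
       rois = read_roi_json(p("rois.json")),
       rater_table = read_rater_csv(p("rater.csv")),
       truth = read_truth_csv(p("truth.csv")),
       displacement = cbind(disp$d_row, disp$d_col),
       true_curves = read_curves_csv(p("true_curves.csv")),
       manifest = manifest)
}
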