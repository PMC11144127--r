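#' Specify a synthetic dual-channel endoscopy scene
#'
#' Describes a recording of a static tissue scene under global camera
#' jitter: a textured white-light channel used for tracking, and a
#' near-infrared (NIR) channel in which each labelled region follows its
#' own ICG kinetic curve. The defaults reproduce the acquisition protocol
#' the pipeline targets: 30 frames per second and at least 120 s of ICG
#' inflow/early washout after a 0.25 mg/kg intravenous bolus (the dose is
#' carried as metadata only).
#'
#' @param frame_size Frame dimensions, `c(rows, cols)` in pixels.
#' @param duration Recording duration (s); `duration * fps` must be a whole
#'   number of frames.
#' @param fps Frame rate (frames/s).
#' @param regions List of regions, each `list(id, label, bbox)` with
#'   `label` one of `"normal"`, `"benign"`, `"malignant"` and `bbox`
#'   `c(r0, c0, r1, c1)` half-open, 0-based, frame-0 coordinates.
#' @param kinetics Named list mapping each tissue class to a
#'   [kinetic_params()] object.
#' @param jitter Integer `n_frames x 2` matrix of per-frame (row, col)
#'   scene displacements relative to frame 0, or `NULL` for a static
#'   camera. See [sinusoidal_jitter()].
#' @param nir_background Background NIR level (a.u.) outside labelled
#'   regions.
#' @param white_noise_sd Gaussian noise sd added to the white channel.
#' @param texture_seed Seed for the white-light texture.
#' @param seed Master RNG seed for sensor noise.
#' @param icg_dose_mg_kg ICG dose metadata (mg/kg); not used numerically.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(frame_size = c(64, 64), duration = 120, fps = 30,
                       regions = default_regions(frame_size),
                       kinetics = default_kinetics(),
                       jitter = NULL,
                       nir_background = 60,
                       white_noise_sd = 0,
                       texture_seed = 1L,
                       seed = 1L,
                       icg_dose_mg_kg = 0.25) {
  assert_that(is.numeric(frame_size) && length(frame_size) == 2L &&
                all(frame_size >= 8), "`frame_size` must be two values >= 8")
  frame_size <- as.integer(frame_size)
  assert_number(duration, "duration", lower = 0, strict_lower = TRUE)
  assert_number(fps, "fps", lower = 0, strict_lower = TRUE)
  n_frames <- duration * fps
  assert_that(abs(n_frames - round(n_frames)) < 1e-9,
              "duration * fps must be an integer frame count (got %g)",
              n_frames)
  n_frames <- as.integer(round(n_frames))
  assert_that(is.list(regions) && length(regions) >= 1L,
              "`regions` must be a non-empty list")
  labels <- vapply(regions, function(r) r$label, character(1))
  assert_that(all(labels %in% c("normal", "benign", "malignant")),
              "region labels must be normal/benign/malignant")
  assert_that(all(labels %in% names(kinetics)),
              "every region label needs an entry in `kinetics`")
  for (kp in kinetics) {
    assert_that(inherits(kp, "kinetic_params"),
                "`kinetics` entries must be kinetic_params objects")
    assert_that(kp$t0 <= duration, "kinetic t0=%g s outside recording window",
                kp$t0)
  }
  if (is.null(jitter)) jitter <- matrix(0L, n_frames, 2L)
  assert_that(is.matrix(jitter) && ncol(jitter) == 2L &&
                nrow(jitter) == n_frames,
              "`jitter` must be an n_frames x 2 matrix")
  assert_that(all(jitter == round(jitter)),
              "`jitter` displacements must be whole pixels")
  jitter <- matrix(as.integer(jitter), n_frames, 2L)
  # every labelled region must remain inside the frame under the jitter
  for (r in regions) {
    b <- r$bbox
    assert_that(is.numeric(b) && length(b) == 4L && b[1] < b[3] && b[2] < b[4],
                "region `%s`: bbox must be c(r0,c0,r1,c1) half-open", r$id)
    assert_that(b[1] >= 0 && b[2] >= 0 && b[3] <= frame_size[1] &&
                  b[4] <= frame_size[2],
                "region `%s`: bbox outside frame", r$id)
    assert_that((b[3] - b[1]) * (b[4] - b[2]) >= 25,
                "region `%s`: area must be >= 25 px", r$id)
    rmin <- b[1] + min(jitter[, 1]); rmax <- b[3] + max(jitter[, 1])
    cmin <- b[2] + min(jitter[, 2]); cmax <- b[4] + max(jitter[, 2])
    assert_that(rmin >= 0 && cmin >= 0 && rmax <= frame_size[1] &&
                  cmax <= frame_size[2],
                "region `%s`: jitter pushes region out of frame", r$id)
  }
  structure(list(frame_size = frame_size, duration = duration, fps = fps,
                 n_frames = n_frames, regions = regions, kinetics = kinetics,
                 jitter = jitter, nir_background = nir_background,
                 white_noise_sd = white_noise_sd,
                 texture_seed = as.integer(texture_seed),
                 seed = as.integer(seed),
                 icg_dose_mg_kg = icg_dose_mg_kg),
            class = "scene_spec")
}

#' Default tissue kinetics for the simulator
#'
#' Three separable kinetic profiles: malignant tissue gets an earlier bolus
#' arrival, an earlier peak (smaller `alpha * beta`) and faster washout than
#' benign; normal mucosa sits in between with a lower amplitude. Magnitudes
#' are simulator configuration, not biological claims.
#'
#' @param noise_sd Per-pixel sensor noise sd applied to every class.
#' @return Named list of [kinetic_params()].
#' @export
default_kinetics <- function(noise_sd = 5) {
  list(
    normal    = kinetic_params(t0 = 8, alpha = 4.0, beta = 3.0,
                               amplitude = 250, baseline = 100,
                               noise_sd = noise_sd),
    benign    = kinetic_params(t0 = 10, alpha = 4.0, beta = 3.0,
                               amplitude = 400, baseline = 100,
                               noise_sd = noise_sd),
    malignant = kinetic_params(t0 = 6, alpha = 3.0, beta = 2.0,
                               amplitude = 450, baseline = 100,
                               noise_sd = noise_sd))
}

#' @rdname scene_spec
#' @export
default_regions <- function(frame_size = c(64, 64)) {
  nr <- frame_size[1]; nc <- frame_size[2]
  h <- max(8L, nr %/% 5L); w <- max(8L, nc %/% 5L)
  list(
    list(id = "normal_1", label = "normal",
         bbox = c(nr %/% 8, nc %/% 8, nr %/% 8 + h, nc %/% 8 + w)),
    list(id = "benign_1", label = "benign",
         bbox = c(nr %/% 8, nc - nc %/% 8 - w, nr %/% 8 + h, nc - nc %/% 8)),
    list(id = "malignant_1", label = "malignant",
         bbox = c(nr - nr %/% 8 - h, nc %/% 8, nr - nr %/% 8, nc %/% 8 + w)))
}

#' Sinusoidal camera jitter
#'
#' Whole-pixel sinusoidal translation in both axes (the column phase is
#' shifted by a quarter period so the camera traces an ellipse).
#'
#' @param n_frames Number of frames.
#' @param amplitude Peak displacement (px).
#' @param period_s Oscillation period (s).
#' @param fps Frame rate.
#' @return Integer `n_frames x 2` displacement matrix, first row `(0, 0)`.
#' @export
sinusoidal_jitter <- function(n_frames, amplitude = 3, period_s = 4,
                              fps = 30) {
  t <- (seq_len(n_frames) - 1) / fps
  w <- 2 * pi / period_s
  cbind(as.integer(round(amplitude * sin(w * t))),
        as.integer(round(amplitude * sin(w * t + pi / 2) - amplitude)))
}

#' Render a synthetic dual-channel recording
#'
#' Renders the white-light and NIR frame stacks of a [scene_spec()] with
#' exact ground truth. The white channel carries a static high-contrast
#' random texture translated rigidly by the jitter series; the NIR channel
#' is a flat background with each labelled region following its class
#' kinetic curve, under the same jitter, plus i.i.d. Gaussian sensor noise.
#' Pixel values are rounded and clipped to the 16-bit range.
#'
#' @param scene A [scene_spec()].
#' @return List with elements `white`, `nir` (integer `rows x cols x frames`
#'   arrays), `mask` (frame-0 label matrix, 0 background / 1..k regions),
#'   `displacement` (the true per-frame jitter, `n_frames x 2`), `times`
#'   (s), `curves` (per-region noise-free generating curves), `region_ids`,
#'   and `scene`.
#' @export
render_video_pair <- function(scene) {
  assert_that(inherits(scene, "scene_spec"), "`scene` must be a scene_spec")
  nr <- scene$frame_size[1]; nc <- scene$frame_size[2]
  nf <- scene$n_frames
  jit <- scene$jitter
  pad <- max(abs(jit), 0L)
  times <- (seq_len(nf) - 1) / scene$fps

  canvas <- with_seed(scene$texture_seed, {
    m <- matrix(stats::runif((nr + 2 * pad) * (nc + 2 * pad), 0, 65535),
                nr + 2 * pad, nc + 2 * pad)
    round(m)
  })

  curves <- lapply(scene$regions, function(r)
    gamma_variate(times, scene$kinetics[[r$label]]))
  names(curves) <- vapply(scene$regions, function(r) r$id, character(1))

  mask <- matrix(0L, nr, nc)
  for (i in seq_along(scene$regions)) {
    b <- scene$regions[[i]]$bbox
    mask[(b[1] + 1):b[3], (b[2] + 1):b[4]] <- i
  }

  white <- array(0L, c(nr, nc, nf))
  nir <- array(0L, c(nr, nc, nf))
  noise_sds <- vapply(scene$regions, function(r)
    scene$kinetics[[r$label]]$noise_sd, numeric(1))

  with_seed(scene$seed, {
    for (f in seq_len(nf)) {
      dr <- jit[f, 1]; dc <- jit[f, 2]
      wl <- canvas[(pad + 1 - dr):(pad + nr - dr),
                   (pad + 1 - dc):(pad + nc - dc)]
      if (scene$white_noise_sd > 0)
        wl <- wl + stats::rnorm(nr * nc, 0, scene$white_noise_sd)
      white[, , f] <- clip_u16(wl)

      nfm <- matrix(scene$nir_background, nr, nc)
      noise_map <- matrix(0, nr, nc)
      for (i in seq_along(scene$regions)) {
        b <- scene$regions[[i]]$bbox
        rows <- (b[1] + 1 + dr):(b[3] + dr)
        cols <- (b[2] + 1 + dc):(b[4] + dc)
        nfm[rows, cols] <- curves[[i]][f]
        noise_map[rows, cols] <- noise_sds[i]
      }
      if (any(noise_map > 0))
        nfm <- nfm + stats::rnorm(nr * nc, 0, 1) * noise_map
      nir[, , f] <- clip_u16(nfm)
    }
  })

  list(white = white, nir = nir, mask = mask, displacement = jit,
       times = times, curves = curves,
       region_ids = names(curves), scene = scene)
}

clip_u16 <- function(m) {
  matrix(as.integer(round(pmin(pmax(m, 0), 65535))), nrow(m), ncol(m))
}

#' Simulate a labelled ROI milestone dataset
#'
#' Draws per-ROI kinetic parameters around class-specific centres, simulates
#' noisy time-fluorescence curves, and runs them through the preprocessing
#' and milestone extraction stages, yielding a classifier-ready feature
#' table with known labels. Each patient carries one lesion class
#' (alternating benign/cancer) plus one normal-tissue reference ROI used
#' for the lesion-minus-normal delta features.
#'
#' @param n_patients Number of patients (default 16).
#' @param rois_per_patient Lesion ROIs per patient (default 4; 64 ROIs for
#'   the defaults).
#' @param kinetics Class centres (named list of [kinetic_params()]); the
#'   defaults give a centre-of-mass separation of several pooled SDs.
#' @param jitter_sd Between-ROI SDs of `t0`, `alpha`, `beta` draws.
#' @param duration,fps Curve sampling window.
#' @param noise_sd Sensor noise on simulated curves (a.u.).
#' @param seed RNG seed.
#' @return `data.frame` with `roi_id`, `patient_id`, `label`
#'   (`benign`/`cancer`) and the ten milestone feature columns.
#' @export
simulate_roi_dataset <- function(n_patients = 16, rois_per_patient = 4,
                                 kinetics = default_kinetics(noise_sd = 0),
                                 jitter_sd = c(t0 = 1, alpha = 0.3,
                                               beta = 0.2),
                                 duration = 60, fps = 30, noise_sd = 5,
                                 seed = 1L) {
  assert_that(n_patients >= 2, "need at least 2 patients")
  times <- seq(0, duration - 1 / fps, by = 1 / fps)
  classes <- rep(c("benign", "malignant"), length.out = n_patients)
  with_seed(seed, {
    rows <- list()
    for (p in seq_len(n_patients)) {
      pid <- sprintf("P%02d", p)
      ref <- roi_features_draw(kinetics[["normal"]], jitter_sd, times,
                               noise_sd, fps)
      for (k in seq_len(rois_per_patient)) {
        les <- roi_features_draw(kinetics[[classes[p]]], jitter_sd, times,
                                 noise_sd, fps)
        feat <- relative_features(les, ref)
        rows[[length(rows) + 1L]] <- data.frame(
          roi_id = sprintf("%s_roi%d", pid, k), patient_id = pid,
          label = if (classes[p] == "malignant") "cancer" else "benign",
          as.data.frame(unclass(feat)[feature_columns()]),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

# One random ROI: jittered kinetic params -> noisy curve -> milestones.
# A draw whose noisy curve has no interpretable perfusion event (possible
# under extreme noise) is discarded and redrawn, as a real pipeline would
# drop an unusable ROI.
roi_features_draw <- function(centre, jitter_sd, times, noise_sd, fps) {
  for (attempt in 1:20) {
    kp <- kinetic_params(
      t0 = max(2.5, stats::rnorm(1, centre$t0, jitter_sd[["t0"]])),
      alpha = max(0.5, stats::rnorm(1, centre$alpha, jitter_sd[["alpha"]])),
      beta = max(0.3, stats::rnorm(1, centre$beta, jitter_sd[["beta"]])),
      amplitude = max(50, stats::rnorm(1, centre$amplitude, 40)),
      baseline = centre$baseline, noise_sd = noise_sd)
    y <- gamma_variate(times, kp)
    if (noise_sd > 0)
      y <- pmax(y + stats::rnorm(length(times), 0, noise_sd), 0)
    curve <- time_intensity_curve(roi_id = "tmp", label = "unknown",
                                  times = times, intensities = y, fps = fps)
    feat <- tryCatch(extract_milestones(preprocess_curve(curve)),
                     error = function(e) NULL)
    if (!is.null(feat)) return(feat)
  }
  stop_fp("could not draw an interpretable ROI curve after 20 attempts")
}
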