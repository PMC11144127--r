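#' Feature-extraction configuration
#'
#' @param smooth_frames Moving-average window (frames; 15 = 0.5 s at
#'   30 fps).
#' @param baseline_seconds Length of the pre-arrival window whose mean
#'   defines the baseline (s); must precede the detected onset.
#' @param onset_threshold Normalized level whose sustained crossing defines
#'   perfusion onset.
#' @param onset_min_duration Minimum time the curve must stay above the
#'   onset threshold (s).
#' @param downslope_window Washout window after the peak used for the
#'   downslope fit (s).
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(smooth_frames = 15L, baseline_seconds = 2,
                           onset_threshold = 0.05, onset_min_duration = 0.5,
                           downslope_window = 60) {
  assert_number(smooth_frames, "smooth_frames", lower = 1)
  assert_number(baseline_seconds, "baseline_seconds", lower = 0)
  assert_number(onset_threshold, "onset_threshold", lower = 0, upper = 1)
  structure(list(smooth_frames = as.integer(smooth_frames),
                 baseline_seconds = baseline_seconds,
                 onset_threshold = onset_threshold,
                 onset_min_duration = onset_min_duration,
                 downslope_window = downslope_window),
            class = "feature_config")
}

# centred moving average with windows clipped at the curve ends
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Normalize a time-intensity curve
#'
#' Smooths the raw curve with a centred moving average, estimates the
#' baseline as the mean over the first `baseline_seconds`, and rescales to
#' `(I - baseline) / (peak - baseline)` so the smoothed curve peaks at 1.
#' Perfusion onset (first sustained crossing of `onset_threshold`) is
#' detected and the baseline window is required to precede it.
#'
#' @param curve A [time_intensity_curve()].
#' @param config A [feature_config()].
#' @return A `normalized_curve`: list with `roi_id`, `label`, `times`,
#'   `normalized`, `baseline`, `peak`, `onset_time`, `smooth_frames`, `fps`.
#' @export
preprocess_curve <- function(curve, config = feature_config()) {
  assert_that(inherits(curve, "time_intensity_curve"),
              "`curve` must be a time_intensity_curve")
  n <- length(curve$times)
  nb <- sum(curve$times < config$baseline_seconds)
  assert_that(n >= nb + 10L,
              "curve too short: %d samples for a %g s baseline window",
              n, config$baseline_seconds)
  s <- moving_average(curve$intensities, config$smooth_frames)
  baseline <- mean(s[curve$times < config$baseline_seconds])
  peak <- max(s)
  if (peak <= baseline)
    stop_fp("no perfusion event: peak (%g) <= baseline (%g) for ROI `%s`",
            peak, baseline, curve$roi_id)
  # a maximum inside the baseline window means the curve only decays:
  # there is no inflow event to normalize against
  if (curve$times[which.max(s)] < config$baseline_seconds)
    stop_fp("no perfusion event: curve maximum precedes the baseline window end for ROI `%s`",
            curve$roi_id)
  z <- (s - baseline) / (peak - baseline)
  onset <- detect_onset(curve$times, z, config)
  if (!is.na(onset) && onset < config$baseline_seconds)
    stop_fp("baseline window (%g s) overlaps perfusion onset (%g s) for ROI `%s`",
            config$baseline_seconds, onset, curve$roi_id)
  structure(list(roi_id = curve$roi_id, label = curve$label,
                 times = curve$times, normalized = z,
                 baseline = baseline, peak = peak,
                 onset_time = onset,
                 smooth_frames = config$smooth_frames,
                 fps = curve$fps),
            class = "normalized_curve")
}

# first time the normalized curve stays above `onset_threshold` for at
# least `onset_min_duration`; NA when never sustained
detect_onset <- function(times, z, config) {
  above <- z > config$onset_threshold
  if (!any(above)) return(NA_real_)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dt <- if (length(times) > 1) times[2] - times[1] else 1
  need <- ceiling(config$onset_min_duration / dt)
  ok <- which(r$values & r$lengths >= need)
  if (!length(ok)) return(NA_real_)
  times[starts[ok[1]]]
}

#' Extract milestone features from a normalized curve
#'
#' Computes the five discriminant bolus-transit milestones:
#' * `t_peak` — time of the (smoothed) curve maximum (s);
#' * `upslope` — least-squares slope of the rising limb between its 10%
#'   and 90% crossings (1/s on the normalized curve);
#' * `downslope` — least-squares slope from the peak to at most
#'   `downslope_window` s later (1/s, non-positive for an interior peak);
#' * `com` — centre of mass: the intensity-weighted mean time over the
#'   recording, normalized intensities clipped at 0 (s);
#' * `skew` — intensity-weighted third standardized moment of time about
#'   `com` (unitless; inflow/washout asymmetry).
#'
#' @param norm A `normalized_curve` from [preprocess_curve()].
#' @param config A [feature_config()].
#' @param recording_id Optional recording identifier, carried along so that
#'   lesion/reference pairs can be checked by [relative_features()].
#' @return A `curve_features` object (named list of the five milestones).
#' @export
extract_milestones <- function(norm, config = feature_config(),
                               recording_id = NA_character_) {
  assert_that(inherits(norm, "normalized_curve"),
              "`norm` must be a normalized_curve")
  z <- norm$normalized
  t <- norm$times
  n <- length(z)
  ip <- which.max(z)
  if (ip == 1L || ip == n)
    stop_fp("curve peak at the %s sample: no interior maximum for ROI `%s`",
            if (ip == 1L) "first" else "last", norm$roi_id)
  t_peak <- t[ip]

  # rising limb: 10% and 90% crossings at or before the peak
  i10 <- which(z[1:ip] >= 0.1)[1]
  i90 <- which(z[1:ip] >= 0.9)[1]
  up_idx <- i10:max(i90, i10 + 1L)
  upslope <- ls_slope(t[up_idx], z[up_idx])

  down_end <- max(which(t <= t[ip] + config$downslope_window))
  down_idx <- ip:max(down_end, ip + 1L)
  downslope <- ls_slope(t[down_idx], z[down_idx])

  # weighted moments over the whole recording: negative (noise) values are
  # clipped at 0, which suppresses baseline mass; windowing at the detected
  # onset instead would bias the third moment beyond its tolerance
  w <- pmax(z, 0)
  tw <- t
  sw <- sum(w)
  if (sw <= 0) stop_fp("zero total intensity (ROI `%s`)", norm$roi_id)
  com <- sum(tw * w) / sw
  v <- sum(w * (tw - com)^2) / sw
  skew <- if (v > 0) sum(w * (tw - com)^3) / sw / v^1.5 else 0

  structure(list(roi_id = norm$roi_id, label = norm$label,
                 recording_id = recording_id,
                 t_peak = t_peak, upslope = upslope, downslope = downslope,
                 skew = skew, com = com),
            class = "curve_features")
}

ls_slope <- function(x, y) {
  xm <- x - mean(x)
  denom <- sum(xm^2)
  if (denom <= 0) return(0)
  sum(xm * (y - mean(y))) / denom
}

milestone_names <- function() c("t_peak", "upslope", "downslope", "skew", "com")

feature_columns <- function() {
  c(milestone_names(), paste0("d_", milestone_names()))
}

#' Lesion-vs-normal relative milestone features
#'
#' Appends, for each of the five milestones, the difference between a
#' lesion ROI and a patient-matched normal-tissue reference ROI from the
#' same recording (`delta = lesion - reference`). Absolute milestones are
#' retained.
#'
#' @param lesion,reference `curve_features` objects from
#'   [extract_milestones()], computed from the same recording.
#' @return The lesion `curve_features` with added `d_t_peak`, `d_upslope`,
#'   `d_downslope`, `d_skew`, `d_com` fields.
#' @export
relative_features <- function(lesion, reference) {
  assert_that(inherits(lesion, "curve_features") &&
                inherits(reference, "curve_features"),
              "both arguments must be curve_features")
  if (!is.na(lesion$recording_id) && !is.na(reference$recording_id) &&
      lesion$recording_id != reference$recording_id)
    stop_fp("lesion (%s) and reference (%s) come from different recordings",
            lesion$recording_id, reference$recording_id)
  out <- unclass(lesion)
  for (m in milestone_names())
    out[[paste0("d_", m)]] <- lesion[[m]] - reference[[m]]
  structure(out, class = "curve_features")
}
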