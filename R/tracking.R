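#' Specify a region of interest
#'
#' An ROI is a rectangular (optionally polygon-annotated) region selected in
#' frame 0 of the white-light channel, carrying the tissue label used
#' downstream.
#'
#' @param id ROI identifier.
#' @param label Tissue label: `"normal"`, `"benign"`, `"malignant"` or
#'   `"unknown"`.
#' @param bbox Bounding box `c(r0, c0, r1, c1)`, half-open, 0-based, in
#'   frame-0 coordinates. Area must be at least 25 px.
#' @param polygon Optional `n x 2` (row, col) polygon kept as annotation.
#' @return An `roi_spec` object.
#' @export
roi_spec <- function(id, label = "unknown", bbox, polygon = NULL) {
  assert_that(is.character(id) || is.numeric(id), "`id` must be a scalar id")
  assert_that(label %in% c("normal", "benign", "malignant", "unknown"),
              "`label` must be normal/benign/malignant/unknown")
  assert_that(is.numeric(bbox) && length(bbox) == 4L,
              "`bbox` must be c(r0, c0, r1, c1)")
  assert_that(bbox[1] < bbox[3] && bbox[2] < bbox[4],
              "`bbox` must be half-open with r0 < r1 and c0 < c1")
  assert_that(all(bbox >= 0), "`bbox` coordinates must be non-negative")
  assert_that((bbox[3] - bbox[1]) * (bbox[4] - bbox[2]) >= 25,
              "ROI area must be >= 25 px")
  structure(list(id = as.character(id), label = label,
                 bbox = as.integer(bbox), polygon = polygon),
            class = "roi_spec")
}

#' Tracking configuration
#'
#' @param search_window Maximum displacement searched per frame (px, each
#'   axis, relative to frame 0).
#' @param min_correlation Frames whose best normalized correlation falls
#'   below this are flagged invalid.
#' @param subpixel Apply 1-D parabolic refinement around the correlation
#'   peak in each axis.
#' @return A list of class `track_config`.
#' @export
track_config <- function(search_window = 15L, min_correlation = 0.5,
                         subpixel = FALSE) {
  assert_number(search_window, "search_window", lower = 1)
  assert_number(min_correlation, "min_correlation", lower = -1, upper = 1)
  structure(list(search_window = as.integer(search_window),
                 min_correlation = min_correlation,
                 subpixel = isTRUE(subpixel)),
            class = "track_config")
}

#' Track an ROI through the white-light channel
#'
#' Estimates the per-frame rigid translation of an ROI by maximising the
#' normalized cross-correlation (NCC) of the frame-0 template within a
#' bounded search window around its frame-0 position. Frames whose best
#' correlation falls below `min_correlation` (including degenerate
#' zero-variance frames, for which NCC is defined as 0) are flagged
#' invalid.
#'
#' @param white Integer/numeric `rows x cols x frames` white-light stack.
#' @param roi An [roi_spec()] valid in frame 0.
#' @param config A [track_config()].
#' @return An `roi_track`: list with `roi_id`, `displacement`
#'   (`n_frames x 2`, frame 0 = `(0,0)`), `valid` (logical), `score`
#'   (best NCC per frame).
#' @export
track_roi <- function(white, roi, config = track_config()) {
  assert_that(is.array(white) && length(dim(white)) == 3L && dim(white)[3] >= 1L,
              "`white` must be a non-empty rows x cols x frames array")
  assert_that(inherits(roi, "roi_spec"), "`roi` must be an roi_spec")
  nr <- dim(white)[1]; nc <- dim(white)[2]; nf <- dim(white)[3]
  b <- roi$bbox
  assert_that(b[3] <= nr && b[4] <= nc,
              "ROI `%s` out of bounds for %dx%d frames", roi$id, nr, nc)
  tmpl <- white[(b[1] + 1):b[3], (b[2] + 1):b[4], 1]
  tmpl <- tmpl - mean(tmpl)
  tss <- sum(tmpl^2)
  th <- nrow(tmpl); tw <- ncol(tmpl)
  W <- config$search_window

  disp <- matrix(0, nf, 2)
  score <- numeric(nf)
  score[1] <- 1
  # search range limited by the frame bounds (0-based displacements)
  dr_range <- max(-W, -b[1]):min(W, nr - b[3])
  dc_range <- max(-W, -b[2]):min(W, nc - b[4])

  for (f in seq_len(nf)[-1]) {
    frame <- white[, , f]
    cc <- matrix(-Inf, length(dr_range), length(dc_range))
    for (i in seq_along(dr_range)) {
      dr <- dr_range[i]
      rows <- (b[1] + 1 + dr):(b[3] + dr)
      for (j in seq_along(dc_range)) {
        dc <- dc_range[j]
        patch <- frame[rows, (b[2] + 1 + dc):(b[4] + dc)]
        pm <- patch - mean(patch)
        pss <- sum(pm^2)
        cc[i, j] <- if (tss <= 0 || pss <= 0) 0 else
          sum(tmpl * pm) / sqrt(tss * pss)
      }
    }
    best <- arrayInd(which.max(cc), dim(cc))
    sc <- cc[best[1], best[2]]
    dhat <- c(dr_range[best[1]], dc_range[best[2]])
    if (config$subpixel) {
      dhat <- dhat + c(parabolic_offset(cc, best, 1L),
                       parabolic_offset(cc, best, 2L))
    }
    disp[f, ] <- dhat
    score[f] <- sc
  }
  structure(list(roi_id = roi$id,
                 displacement = disp,
                 valid = score >= config$min_correlation,
                 score = score,
                 config = config),
            class = "roi_track")
}

# 1-D parabolic interpolation of the correlation peak along one axis;
# returns a sub-pixel offset in (-0.5, 0.5), or 0 at the search boundary.
parabolic_offset <- function(cc, best, axis) {
  idx <- best[axis]
  n <- dim(cc)[axis]
  if (idx <= 1L || idx >= n) return(0)
  pick <- function(k) if (axis == 1L) cc[k, best[2]] else cc[best[1], k]
  y0 <- pick(idx - 1L); y1 <- pick(idx); y2 <- pick(idx + 1L)
  den <- y0 - 2 * y1 + y2
  if (!is.finite(den) || abs(den) < 1e-12) return(0)
  off <- 0.5 * (y0 - y2) / den
  max(min(off, 0.5), -0.5)
}

#' Construct a time-intensity curve
#'
#' @param roi_id ROI identifier.
#' @param label Tissue label.
#' @param times Sample times (s), `frame_index / fps`.
#' @param intensities Mean ROI intensities (a.u., non-negative).
#' @param fps Frame rate.
#' @param valid Per-sample validity flags (default all valid).
#' @return A `time_intensity_curve` object.
#' @export
time_intensity_curve <- function(roi_id, label, times, intensities, fps,
                                 valid = rep(TRUE, length(times))) {
  assert_that(length(times) == length(intensities),
              "`times` and `intensities` lengths differ")
  assert_that(all(intensities >= 0), "intensities must be non-negative")
  structure(list(roi_id = as.character(roi_id), label = label,
                 times = as.numeric(times),
                 intensities = as.numeric(intensities),
                 fps = fps, valid = valid),
            class = "time_intensity_curve")
}

#' Extract the NIR time-intensity curve of a tracked ROI
#'
#' For each valid frame, averages the NIR intensity over the ROI footprint
#' displaced by the (rounded) tracked displacement. Invalid frames are
#' filled by linear interpolation in time between the nearest valid
#' neighbours (endpoints hold the nearest valid value), or removed when
#' `invalid_policy = "drop"`.
#'
#' @param nir NIR `rows x cols x frames` stack, frame-synchronous with the
#'   tracked white channel.
#' @param track An `roi_track` from [track_roi()].
#' @param roi The matching [roi_spec()].
#' @param fps Frame rate (default 30).
#' @param invalid_policy `"interpolate"` (default) or `"drop"`.
#' @return A [time_intensity_curve()].
#' @export
extract_curve <- function(nir, track, roi, fps = 30,
                          invalid_policy = c("interpolate", "drop")) {
  invalid_policy <- match.arg(invalid_policy)
  assert_that(is.array(nir) && length(dim(nir)) == 3L,
              "`nir` must be a rows x cols x frames array")
  assert_that(inherits(track, "roi_track"), "`track` must be an roi_track")
  assert_that(inherits(roi, "roi_spec"), "`roi` must be an roi_spec")
  nf <- dim(nir)[3]
  assert_that(nrow(track$displacement) == nf,
              "track length (%d) does not match stack (%d frames)",
              nrow(track$displacement), nf)
  assert_that(any(track$valid), "all frames invalid: cannot extract a curve")
  nr <- dim(nir)[1]; nc <- dim(nir)[2]
  b <- roi$bbox
  vals <- rep(NA_real_, nf)
  for (f in which(track$valid)) {
    d <- round(track$displacement[f, ])
    r0 <- b[1] + d[1]; r1 <- b[3] + d[1]
    c0 <- b[2] + d[2]; c1 <- b[4] + d[2]
    assert_that(r0 >= 0 && c0 >= 0 && r1 <= nr && c1 <= nc,
                "displaced ROI `%s` outside frame at frame %d", roi$id, f - 1L)
    vals[f] <- mean(nir[(r0 + 1):r1, (c0 + 1):c1, f])
  }
  times <- (seq_len(nf) - 1) / fps
  if (invalid_policy == "drop") {
    keep <- track$valid
    return(time_intensity_curve(roi$id, roi$label, times[keep], vals[keep],
                                fps, valid = rep(TRUE, sum(keep))))
  }
  if (anyNA(vals)) {
    ok <- which(!is.na(vals))
    vals <- stats::approx(times[ok], vals[ok], xout = times,
                          rule = 2)$y
  }
  time_intensity_curve(roi$id, roi$label, times, vals, fps,
                       valid = track$valid)
}
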