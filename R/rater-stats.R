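#' Build an items x categories agreement count matrix
#'
#' Accepts either a ready count matrix (items in rows, categories in
#' columns) or a long rater table with `polyp_id` and `answer` columns.
#' Every item must have been rated by the same number of raters.
#'
#' @param x Count matrix or long `data.frame`.
#' @param categories Category names (columns); defaults to
#'   `c("benign", "cancer")` for rater tables.
#' @return An `agreement_counts` matrix with attribute `n_raters`.
#' @export
agreement_counts <- function(x, categories = NULL) {
  if (is.data.frame(x)) {
    assert_that(all(c("polyp_id", "answer") %in% names(x)),
                "rater table needs `polyp_id` and `answer` columns")
    categories <- categories %||% sort(unique(x$answer))
    counts <- table(factor(x$polyp_id, levels = unique(x$polyp_id)),
                    factor(x$answer, levels = categories))
    m <- matrix(as.integer(counts), nrow(counts), ncol(counts),
                dimnames = dimnames(counts))
  } else {
    m <- as.matrix(x)
    assert_that(is.numeric(m) && all(m >= 0) && all(m == round(m)),
                "counts must be non-negative integers")
    if (!is.null(categories)) colnames(m) <- categories
  }
  assert_that(nrow(m) >= 2L, "need at least 2 items")
  assert_that(ncol(m) >= 2L, "need at least 2 categories")
  rs <- rowSums(m)
  assert_that(all(rs == rs[1]), "every item must have the same rater count")
  assert_that(rs[1] >= 2L, "need at least 2 raters per item")
  structure(m, n_raters = as.integer(rs[1]), class = "agreement_counts")
}

#' Fleiss multi-rater kappa with a large-sample confidence interval
#'
#' Chance-corrected agreement among a fixed panel of `n` raters assigning
#' `N` items to nominal categories. With `n_ij` the number of raters
#' placing item `i` in category `j` and `p_j` the overall category
#' proportions:
#' \deqn{P_i = \frac{\sum_j n_{ij}^2 - n}{n(n-1)}, \quad
#'       \bar{P} = \frac{1}{N}\sum_i P_i, \quad
#'       P_e = \sum_j p_j^2, \quad
#'       \kappa = \frac{\bar{P} - P_e}{1 - P_e}}
#' The standard error uses the large-sample form
#' \deqn{SE^2 = \frac{2}{Nn(n-1)} \cdot
#'       \frac{P_e - (2n-3)P_e^2 + 2(n-2)\sum_j p_j^3}{(1 - P_e)^2}}
#' and the 95% CI is \eqn{\kappa \pm 1.96\,SE}. A one-sided test of
#' \eqn{\kappa = 0} (z = kappa/SE) provides the p-value.
#'
#' @param counts An [agreement_counts()] matrix (or anything it accepts).
#' @param conf_level Confidence level (default 0.95).
#' @return A `kappa_result`: `kappa`, `se`, `ci` (lower, upper),
#'   `p_observed`, `p_expected`, `z`, `p_value`, `band`, `n_items`,
#'   `n_raters`.
#' @examples
#' m <- rbind(c(2, 1), c(1, 2))
#' fleiss_kappa(m)$kappa  # -1/3
#' @export
fleiss_kappa <- function(counts, conf_level = 0.95) {
  counts <- agreement_counts(counts)
  n <- attr(counts, "n_raters")
  N <- nrow(counts)
  p_i <- (rowSums(counts^2) - n) / (n * (n - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(counts) / (N * n)
  p_e <- sum(p_j^2)
  if (p_e >= 1 - 1e-12)
    stop_fp("degenerate: agreement undefined (all votes in one category)")
  kappa <- (p_bar - p_e) / (1 - p_e)
  se2 <- (2 / (N * n * (n - 1))) *
    (p_e - (2 * n - 3) * p_e^2 + 2 * (n - 2) * sum(p_j^3)) / (1 - p_e)^2
  se <- sqrt(se2)
  z <- kappa / se
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(kappa = kappa, se = se,
                 ci = c(lower = kappa - zq * se, upper = kappa + zq * se),
                 p_observed = p_bar, p_expected = p_e,
                 z = z, p_value = stats::pnorm(z, lower.tail = FALSE),
                 band = interpret_kappa(kappa),
                 n_items = N, n_raters = n,
                 conf_level = conf_level),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf(
    "Fleiss kappa = %.3f (%.0f%% CI %.3f to %.3f), '%s' agreement\n",
    x$kappa, 100 * x$conf_level, x$ci[1], x$ci[2], x$band))
  cat(sprintf("  observed agreement %.3f, expected %.3f, z = %.2f, p %s\n",
              x$p_observed, x$p_expected, x$z,
              if (x$p_value < 0.001) "< 0.001" else
                sprintf("= %.3f", x$p_value)))
  invisible(x)
}

#' Interpret a kappa value on the conventional agreement bands
#'
#' Bands: `< 0.20` poor, `0.21-0.40` fair, `0.41-0.60` moderate,
#' `0.61-0.80` good, `0.81-1.0` very good. The conventional table leaves
#' gaps (e.g. 0.205): such values are assigned to the lower band with a
#' warning.
#'
#' @param kappa Kappa value (`<= 1`).
#' @return Band label (character).
#' @export
interpret_kappa <- function(kappa) {
  assert_that(is.numeric(kappa) && length(kappa) == 1L && kappa <= 1 + 1e-12,
              "`kappa` must be a single value <= 1")
  lows <- c(0.21, 0.41, 0.61, 0.81)
  bands <- c("poor", "fair", "moderate", "good", "very good")
  idx <- findInterval(kappa, lows) + 1L
  gaps <- rbind(c(0.20, 0.21), c(0.40, 0.41), c(0.60, 0.61), c(0.80, 0.81))
  in_gap <- any(kappa > gaps[, 1] & kappa < gaps[, 2])
  if (in_gap)
    warning(sprintf(
      "kappa = %.3f falls in a gap of the band table; assigned to '%s'",
      kappa, bands[idx]), call. = FALSE)
  bands[idx]
}

#' Likert confidence frequency table
#'
#' Per-polyp counts and percentages of the 1-5 confidence levels, and the
#' mean score (reported to 2 decimals, half away from zero).
#'
#' @param table Long rater table with `polyp_id` and `confidence` columns.
#' @return `data.frame` with one row per polyp: `polyp_id`, `n`,
#'   `count_1`..`count_5`, `pct_1`..`pct_5`, `mean_score` (raw) and
#'   `mean_reported`.
#' @export
likert_summary <- function(table) {
  assert_that(is.data.frame(table) &&
                all(c("polyp_id", "confidence") %in% names(table)),
              "`table` needs `polyp_id` and `confidence` columns")
  assert_that(all(table$confidence %in% 1:5),
              "confidence scores must be integers 1..5")
  polyps <- unique(table$polyp_id)
  rows <- lapply(polyps, function(p) {
    conf <- table$confidence[table$polyp_id == p]
    cnt <- tabulate(conf, nbins = 5L)
    m <- mean(conf)
    out <- data.frame(polyp_id = p, n = length(conf))
    out[paste0("count_", 1:5)] <- as.list(cnt)
    out[paste0("pct_", 1:5)] <- as.list(round_half_up(100 * cnt /
                                                        length(conf), 1))
    out$mean_score <- m
    out$mean_reported <- round_half_up(m, 2)
    out
  })
  do.call(rbind, rows)
}

#' Per-rater and per-group diagnostic performance
#'
#' Scores every rater's benign/cancer answers against pathology truth
#' (cancer positive), then aggregates to grade / interest groups as the
#' mean of per-rater percentages with min-max ranges.
#'
#' @param table Long rater table with `rater_id`, `polyp_id`, `answer`,
#'   `truth` and optionally `grade` and `complex_interest` columns.
#' @return List with `per_rater` and `groups` data frames.
#' @export
rater_performance <- function(table) {
  assert_that(is.data.frame(table) &&
                all(c("rater_id", "polyp_id", "answer", "truth") %in%
                      names(table)),
              "`table` needs rater_id, polyp_id, answer, truth columns")
  raters <- unique(table$rater_id)
  per <- lapply(raters, function(r) {
    sub <- table[table$rater_id == r, ]
    ev <- evaluate_calls(sub$answer, sub$truth)
    data.frame(rater_id = r,
               grade = if ("grade" %in% names(sub)) sub$grade[1] else NA,
               complex_interest = if ("complex_interest" %in% names(sub))
                 sub$complex_interest[1] else NA,
               accuracy = ev$accuracy, sensitivity = ev$sensitivity,
               specificity = ev$specificity,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)

  group_rows <- list()
  add_group <- function(name, idx) {
    if (!any(idx)) {
      warning(sprintf("group '%s' has no members; omitted", name),
              call. = FALSE)
      return()
    }
    g <- per[idx, ]
    summ <- function(v) c(mean = mean(v, na.rm = TRUE),
                          min = min(v, na.rm = TRUE),
                          max = max(v, na.rm = TRUE))
    a <- summ(g$accuracy); s <- summ(g$sensitivity); p <- summ(g$specificity)
    group_rows[[length(group_rows) + 1L]] <<- data.frame(
      group = name, n = nrow(g),
      accuracy = a["mean"], accuracy_min = a["min"], accuracy_max = a["max"],
      sensitivity = s["mean"], sensitivity_min = s["min"],
      sensitivity_max = s["max"],
      specificity = p["mean"], specificity_min = p["min"],
      specificity_max = p["max"],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  add_group("all", rep(TRUE, nrow(per)))
  if (!all(is.na(per$grade)))
    for (g in unique(per$grade)) add_group(g, per$grade %in% g)
  if (!all(is.na(per$complex_interest)))
    add_group("complex_interest", isTRUE(per$complex_interest) |
                per$complex_interest %in% TRUE)
  list(per_rater = per, groups = do.call(rbind, group_rows))
}

#' Per-polyp majority decision versus pathology
#'
#' @param table Long rater table with `polyp_id`, `answer` and optionally
#'   `truth` columns. An exact 50/50 split is flagged `even` and counted as
#'   not correct.
#' @return `data.frame` per polyp (`majority`, `share_pct`, `even`,
#'   `correct`) with attributes `n_correct` and `n_even`.
#' @export
majority_decision <- function(table) {
  assert_that(is.data.frame(table) &&
                all(c("polyp_id", "answer") %in% names(table)),
              "`table` needs `polyp_id` and `answer` columns")
  polyps <- unique(table$polyp_id)
  rows <- lapply(polyps, function(p) {
    sub <- table[table$polyp_id == p, ]
    nb <- sum(sub$answer == "benign"); nc <- sum(sub$answer == "cancer")
    even <- nb == nc
    maj <- if (even) "even" else if (nb > nc) "benign" else "cancer"
    share <- 100 * max(nb, nc) / (nb + nc)
    truth <- if ("truth" %in% names(sub)) sub$truth[1] else NA_character_
    data.frame(polyp_id = p, n_benign = nb, n_cancer = nc,
               majority = maj, share_pct = round_half_up(share),
               even = even, truth = truth,
               correct = !even && !is.na(truth) && maj == truth,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_correct") <- sum(out$correct)
  attr(out, "n_even") <- sum(out$even)
  out
}

#' Spearman rank-order correlation
#'
#' Rank correlation with average-rank tie handling: Pearson correlation of
#' the rank vectors, p-value from the t approximation with `n - 2` degrees
#' of freedom.
#'
#' @param x,y Equal-length numeric/ordinal vectors (`n >= 3`).
#' @return List `rho`, `p_value`, `n`, `degenerate` (TRUE with a warning,
#'   and `rho = NA`, when either series has zero variance).
#' @export
spearman_correlation <- function(x, y) {
  assert_that(length(x) == length(y), "`x` and `y` lengths differ")
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  assert_that(n >= 3L, "need at least 3 paired observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("Spearman correlation undefined: zero variance", call. = FALSE)
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                degenerate = TRUE))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  tval <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-15))
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  list(rho = rho, p_value = min(p, 1), n = n, degenerate = FALSE)
}

#' Lesion size-estimation error
#'
#' Signed percentage error of mean size estimates against resected
#' pathology size: `(estimate - actual) / actual * 100`.
#'
#' @param sizes `data.frame` with `polyp_id`, `estimate_mm`, `actual_mm`
#'   (actual must be positive and present).
#' @return `data.frame` with per-polyp `signed_pct_error` and
#'   `abs_pct_error`, plus attributes `mean_signed_pct` and
#'   `mean_abs_pct`.
#' @export
size_error <- function(sizes) {
  assert_that(is.data.frame(sizes) &&
                all(c("polyp_id", "estimate_mm", "actual_mm") %in%
                      names(sizes)),
              "`sizes` needs polyp_id, estimate_mm, actual_mm columns")
  assert_that(!anyNA(sizes$actual_mm) && all(sizes$actual_mm > 0),
              "`actual_mm` must be present and positive")
  err <- (sizes$estimate_mm - sizes$actual_mm) / sizes$actual_mm * 100
  out <- data.frame(polyp_id = sizes$polyp_id,
                    estimate_mm = sizes$estimate_mm,
                    actual_mm = sizes$actual_mm,
                    signed_pct_error = err,
                    abs_pct_error = abs(err))
  attr(out, "mean_signed_pct") <- mean(err)
  attr(out, "mean_abs_pct") <- mean(abs(err))
  out
}
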