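#' Full rater-statistics report
#'
#' Runs the complete clinical-judgement analysis on a long rater table:
#' Fleiss kappa (overall and per grade group), Likert confidence tables,
#' per-rater/group diagnostic performance, majority decisions versus
#' pathology, the confidence-vs-correctness Spearman correlation, and
#' (when size data are supplied) size-estimation error. Optionally writes
#' `report.json` and `report.md` to a directory.
#'
#' @param table Long rater table (`rater_id, polyp_id, answer, confidence`,
#'   optionally `grade`, `truth`).
#' @param truth Optional truth table (`polyp_id, pathology`) merged in when
#'   the rater table has no `truth` column.
#' @param sizes Optional size table (`polyp_id, estimate_mm, actual_mm`).
#' @param out_dir Optional output directory for `report.json`/`report.md`.
#' @return The report as a nested list, invisibly when written to disk.
#' @export
rater_stats_report <- function(table, truth = NULL, sizes = NULL,
                               out_dir = NULL) {
  if (!"truth" %in% names(table) && !is.null(truth)) {
    idx <- match(table$polyp_id, truth$polyp_id)
    assert_that(!anyNA(idx), "polyp ids in rater table missing from truth")
    table$truth <- truth$pathology[idx]
  }
  report <- list()

  kap <- fleiss_kappa(agreement_counts(table))
  report$kappa <- list(overall = kappa_to_list(kap))
  if ("grade" %in% names(table)) {
    for (g in unique(table$grade)) {
      sub <- table[table$grade == g, ]
      res <- tryCatch(kappa_to_list(fleiss_kappa(agreement_counts(sub))),
                      error = function(e) list(error = conditionMessage(e)))
      report$kappa[[g]] <- res
    }
  }

  report$likert <- likert_summary(table)
  report$majority <- {
    mj <- majority_decision(table)
    list(table = mj, n_correct = attr(mj, "n_correct"),
         n_even = attr(mj, "n_even"), n_items = nrow(mj))
  }

  if ("truth" %in% names(table)) {
    perf <- rater_performance(table)
    report$performance <- perf
    correct <- as.numeric(table$answer == table$truth)
    sp <- spearman_correlation(table$confidence, correct)
    report$spearman_confidence_correct <- sp
  }

  if (!is.null(sizes)) {
    se <- size_error(sizes)
    report$size_error <- list(
      table = se,
      mean_signed_pct = attr(se, "mean_signed_pct"),
      mean_abs_pct = attr(se, "mean_abs_pct"))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, force = TRUE,
                         dataframe = "rows")
    writeLines(render_report_md(report), file.path(out_dir, "report.md"))
    return(invisible(report))
  }
  report
}

kappa_to_list <- function(k) {
  list(kappa = k$kappa, se = k$se, ci_lower = unname(k$ci[1]),
       ci_upper = unname(k$ci[2]), p_observed = k$p_observed,
       p_expected = k$p_expected, p_value = k$p_value, band = k$band,
       n_items = k$n_items, n_raters = k$n_raters)
}

render_report_md <- function(report) {
  out <- c("# Rater statistics report", "")
  k <- report$kappa$overall
  out <- c(out, "## Inter-rater agreement", "",
           sprintf("Fleiss kappa = %.3f (95%% CI %.3f to %.3f), '%s' agreement over %d items x %d raters.",
                   k$kappa, k$ci_lower, k$ci_upper, k$band, k$n_items,
                   k$n_raters), "")
  extra <- setdiff(names(report$kappa), "overall")
  for (g in extra) {
    kg <- report$kappa[[g]]
    if (!is.null(kg$error)) next
    out <- c(out, sprintf("- %s: kappa = %.3f (%.3f to %.3f), '%s'",
                          g, kg$kappa, kg$ci_lower, kg$ci_upper, kg$band))
  }
  mj <- report$majority
  out <- c(out, "", "## Majority decisions", "",
           sprintf("Majority correct for %d of %d polyps; %d evenly split.",
                   mj$n_correct, mj$n_items, mj$n_even), "")
  out <- c(out, "## Likert confidence", "",
           "polyp | mean score | counts 1..5",
           "----- | ---------- | -----------")
  for (i in seq_len(nrow(report$likert))) {
    r <- report$likert[i, ]
    out <- c(out, sprintf("%s | %.2f | %s", r$polyp_id, r$mean_reported,
                          paste(r[paste0("count_", 1:5)], collapse = "/")))
  }
  if (!is.null(report$performance)) {
    out <- c(out, "", "## Diagnostic performance (per-rater means)", "",
             "group | n | accuracy % | sensitivity % | specificity %",
             "----- | - | ---------- | ------------- | -------------")
    g <- report$performance$groups
    for (i in seq_len(nrow(g)))
      out <- c(out, sprintf(
        "%s | %d | %.0f (%.0f-%.0f) | %.0f (%.0f-%.0f) | %.0f (%.0f-%.0f)",
        g$group[i], g$n[i], round_half_up(g$accuracy[i]),
        g$accuracy_min[i], g$accuracy_max[i],
        round_half_up(g$sensitivity[i]), g$sensitivity_min[i],
        g$sensitivity_max[i], round_half_up(g$specificity[i]),
        g$specificity_min[i], g$specificity_max[i]))
  }
  if (!is.null(report$spearman_confidence_correct)) {
    sp <- report$spearman_confidence_correct
    out <- c(out, "", sprintf(
      "Spearman correlation (confidence vs correctness): rho = %.3f, p = %.3g, n = %d.",
      sp$rho, sp$p_value, sp$n))
  }
  if (!is.null(report$size_error)) {
    out <- c(out, "", "## Size estimation", "",
             sprintf("Mean signed error %.1f%%; mean absolute error %.1f%%.",
                     report$size_error$mean_signed_pct,
                     report$size_error$mean_abs_pct))
  }
  out
}
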