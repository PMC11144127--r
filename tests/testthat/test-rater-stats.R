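test_that("Fleiss kappa reproduces the published panel value exactly", {
  k <- fleiss_kappa(study_agreement_counts())
  expect_equal(round(k$kappa, 3), 0.261)
  expect_equal(round(unname(k$ci["lower"]), 3), 0.237)
  expect_equal(round(unname(k$ci["upper"]), 3), 0.285)
  expect_equal(k$band, "fair")
  expect_lt(k$p_value, 0.001)
  expect_equal(k$n_items, 14)
  expect_equal(k$n_raters, 32)
})

test_that("Fleiss kappa matches hand-evaluated and boundary cases", {
  # 3 raters, 2 items, counts [[2,1],[1,2]]
  k <- fleiss_kappa(rbind(c(2, 1), c(1, 2)))
  expect_equal(k$p_observed, 1 / 3)
  expect_equal(k$p_expected, 1 / 2)
  expect_equal(k$kappa, -1 / 3)
  # unanimity on every item, both categories used
  k1 <- fleiss_kappa(rbind(c(5, 0), c(0, 5), c(5, 0)))
  expect_equal(k1$kappa, 1)
  expect_true(k1$ci[1] <= 1 && k1$ci[2] >= 1)
  # all votes in one category: chance agreement is total, kappa undefined
  expect_error(fleiss_kappa(rbind(c(5, 0), c(5, 0))), "degenerate")
  expect_error(agreement_counts(rbind(c(2, 1), c(3, 1))), "same rater count")
})

test_that("kappa is invariant to item order and category swap", {
  m <- study_agreement_counts()
  k0 <- fleiss_kappa(m)$kappa
  set.seed(2)
  expect_equal(fleiss_kappa(m[sample(nrow(m)), ])$kappa, k0)
  expect_equal(fleiss_kappa(m[, 2:1])$kappa, k0)
})

test_that("interpretation bands follow the published thresholds", {
  expect_equal(interpret_kappa(0.261), "fair")
  expect_equal(interpret_kappa(0.187), "poor")
  expect_equal(interpret_kappa(1.0), "very good")
  expect_equal(interpret_kappa(-0.2), "poor")
  expect_equal(interpret_kappa(0.41), "moderate")
  expect_equal(interpret_kappa(0.80), "good")
  expect_warning(band <- interpret_kappa(0.205), "gap")
  expect_equal(band, "poor")
  expect_warning(interpret_kappa(0.605), "gap")
})

test_that("Likert summaries reproduce all 14 published means", {
  votes <- study_vote_table()
  ls <- likert_summary(study_long_table())
  expect_equal(ls$mean_reported, votes$mean_likert_printed)
  expect_equal(ls$count_1 + ls$count_2 + ls$count_3 + ls$count_4 +
                 ls$count_5, rep(32L, 14))
  # worked rows: counts (0,4,16,11,1) -> 3.28; (0,1,9,16,6) -> 3.84
  expect_equal(ls$mean_reported[1], 3.28)
  expect_equal(ls$mean_reported[8], 3.84)
  # degenerate: all raters at level 3
  flat <- data.frame(polyp_id = 1, confidence = rep(3L, 32))
  lf <- likert_summary(flat)
  expect_equal(lf$mean_reported, 3.00)
  expect_equal(lf$pct_3, 100)
})

test_that("majority decisions reproduce the published 6/14 with one even split", {
  mj <- majority_decision(study_long_table())
  expect_equal(attr(mj, "n_correct"), 6)
  expect_equal(attr(mj, "n_even"), 1)
  expect_true(mj$even[14])
  expect_equal(mj$share_pct[14], 50)
  expect_false(mj$correct[14])   # even split counts as not correct
  # in 2/3 polyps with > 90% agreement the majority was wrong
  high <- mj[mj$share_pct > 90 & !mj$even, ]
  expect_equal(nrow(high), 3)
  expect_equal(sum(!high$correct), 2)
  # unanimity
  un <- majority_decision(data.frame(polyp_id = rep(1, 8),
                                     answer = rep("cancer", 8),
                                     truth = rep("cancer", 8)))
  expect_equal(un$share_pct, 100)
  expect_false(un$even)
  expect_true(un$correct)
})

test_that("per-rater performance: forced cases and brute-force oracle", {
  tab <- simulate_rater_table(rater_model_params(n_raters = 1, n_items = 14,
                                                 skill = 10, seed = 1))
  perf <- rater_performance(tab)
  expect_equal(perf$per_rater$accuracy, 100)
  expect_equal(perf$per_rater$sensitivity, 100)
  expect_equal(perf$per_rater$specificity, 100)

  # all-cancer answers on a 7/7 panel: 50 / 100 / 0
  all_cancer <- data.frame(rater_id = "r1", polyp_id = 1:14,
                           answer = "cancer",
                           truth = rep(c("cancer", "benign"), each = 7))
  p2 <- rater_performance(all_cancer)$per_rater
  expect_equal(c(p2$accuracy, p2$sensitivity, p2$specificity),
               c(50, 100, 0))

  # random tables: group means equal a naive loop
  tab3 <- simulate_rater_table(rater_model_params(n_raters = 9, n_items = 10,
                                                  skill = 0.4, seed = 8))
  perf3 <- rater_performance(tab3)
  for (g in unique(tab3$grade)) {
    accs <- vapply(unique(tab3$rater_id[tab3$grade == g]), function(r) {
      sub <- tab3[tab3$rater_id == r, ]
      oracle_metrics(sub$answer, sub$truth)$accuracy
    }, numeric(1))
    row <- perf3$groups[perf3$groups$group == g, ]
    expect_equal(row$accuracy, mean(accs))
    expect_equal(row$accuracy_min, min(accs))
    expect_equal(row$accuracy_max, max(accs))
  }
})

test_that("spearman correlation: exact cases and naive-rank oracle", {
  expect_equal(spearman_correlation(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_correlation(1:10, rev(1:10))$rho, -1)
  set.seed(21)
  for (i in 1:10) {
    x <- sample(1:5, 30, replace = TRUE)
    y <- sample(0:1, 30, replace = TRUE)
    if (stats::var(x) == 0 || stats::var(y) == 0) next
    sp <- spearman_correlation(x, y)
    expect_equal(sp$rho, stats::cor(oracle_rank(x), oracle_rank(y)))
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(sp$rho, unname(ct$estimate), tolerance = 1e-12)
  }
  expect_warning(sp0 <- spearman_correlation(rep(2, 5), 1:5),
                 "zero variance")
  expect_true(sp0$degenerate && is.na(sp0$rho))
  expect_error(spearman_correlation(1:2, 1:2), "at least 3")
})

test_that("size errors reproduce the published per-polyp values", {
  st <- study_size_table()
  se <- size_error(data.frame(polyp_id = st$polyp_id,
                              estimate_mm = st$estimate_mm,
                              actual_mm = st$actual_mm))
  expect_equal(se$signed_pct_error[1], -50)        # 60 vs 120 mm
  expect_equal(se$signed_pct_error[3], -4.3, tolerance = 0.05)
  expect_equal(nrow(se), 6)
  # recomputed averages (flagged in docs; the published 20%/15% round these)
  expect_equal(attr(se, "mean_abs_pct"), 21.4, tolerance = 0.05)
  expect_equal(mean(se$abs_pct_error[st$fully_visible]), 15.6,
               tolerance = 0.05)
  ze <- size_error(data.frame(polyp_id = 1, estimate_mm = 30,
                              actual_mm = 30))
  expect_equal(ze$signed_pct_error, 0)
  expect_error(size_error(data.frame(polyp_id = 1, estimate_mm = 10,
                                     actual_mm = NA)), "actual_mm")
})

test_that("random independent raters give kappa centred at 0 (Monte Carlo)", {
  ks <- vapply(1:400, function(r) {
    fleiss_kappa(agreement_counts(random_rater_table(seed = 5000 + r)))$kappa
  }, numeric(1))
  mc_se <- stats::sd(ks) / sqrt(length(ks))
  expect_lt(abs(mean(ks)), 4 * mc_se + 0.002)
})

test_that("kappa CI brackets the estimate and shrinks with more items", {
  widths <- vapply(c(14, 56, 224), function(N) {
    tab <- simulate_rater_table(rater_model_params(n_raters = 32,
                                                   n_items = N,
                                                   skill = 0.8, seed = 99))
    k <- fleiss_kappa(agreement_counts(tab))
    expect_true(k$ci[1] <= k$kappa && k$kappa <= k$ci[2])
    unname(k$ci[2] - k$ci[1])
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("rater_stats_report assembles every section and writes outputs", {
  tab <- simulate_rater_table(rater_model_params(n_raters = 10,
                                                 n_items = 14,
                                                 skill = 0.6, seed = 13))
  sizes <- data.frame(polyp_id = 1:4, estimate_mm = c(20, 35, 50, 12),
                      actual_mm = c(25, 30, 50, 16))
  dir <- withr::local_tempdir()
  rep <- rater_stats_report(tab, sizes = sizes, out_dir = dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "report.md")))
  expect_setequal(names(rep$kappa), c("overall", "consultant",
                                      "late_training", "middle_training"))
  expect_equal(nrow(rep$likert), 14)
  expect_equal(rep$majority$n_items, 14)
  expect_false(is.null(rep$performance))
  expect_false(is.null(rep$spearman_confidence_correct))
  expect_equal(rep$size_error$table$signed_pct_error[1], -20)
})
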