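small_space <- function() {
  ensemble_search_space(trees = 50L, depth = 2L, families = "bag")
}

test_that("single-class datasets and tiny patient counts are rejected", {
  ds <- simulate_roi_dataset(n_patients = 6, rois_per_patient = 2, seed = 1)
  one <- ds[ds$label == "benign", ]
  expect_error(train_ensemble(roi_dataset(one)), "single-class")
  expect_error(train_ensemble(roi_dataset(ds), folds = 10),
               "fewer patients")
  bad <- ds; bad$com[1] <- NA
  expect_error(roi_dataset(bad), "missing values")
})

test_that("separable dataset: >= 0.95 CV accuracy, matching a nearest-centroid oracle", {
  ds <- simulate_roi_dataset(seed = 42)   # 64 ROIs / 16 patients
  model <- train_ensemble(roi_dataset(ds), folds = 5,
                          search_space = small_space(), seed = 7)
  expect_gte(model$cv_report$mean_cv_accuracy, 0.95)

  # independent oracle: leave-one-patient-out nearest centroid on com
  correct <- 0
  for (p in unique(ds$patient_id)) {
    tr <- ds[ds$patient_id != p, ]; te <- ds[ds$patient_id == p, ]
    cen <- tapply(tr$com, tr$label, mean)
    pred <- names(cen)[apply(abs(outer(te$com, cen, "-")), 1, which.min)]
    correct <- correct + sum(pred == te$label)
  }
  expect_gte(correct / nrow(ds), 0.95)
})

test_that("label permutation drops CV accuracy to chance", {
  ds <- simulate_roi_dataset(seed = 42)
  accs <- vapply(1:10, function(r) {
    perm <- ds
    set.seed(100 + r)
    perm$label <- sample(ds$label)
    m <- train_ensemble(roi_dataset(perm), folds = 5,
                        search_space = small_space(), seed = 7)
    m$cv_report$mean_cv_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("training is seeded and row-order independent", {
  ds <- simulate_roi_dataset(n_patients = 8, rois_per_patient = 2, seed = 3)
  m1 <- train_ensemble(roi_dataset(ds), folds = 4,
                       search_space = small_space(), seed = 5)
  m2 <- train_ensemble(roi_dataset(ds), folds = 4,
                       search_space = small_space(), seed = 5)
  expect_equal(m1$cv_report$grid, m2$cv_report$grid)
  # shuffling rows must not change fold membership (folds are patient-keyed)
  set.seed(9)
  shuf <- ds[sample(nrow(ds)), ]
  m3 <- train_ensemble(roi_dataset(shuf), folds = 4,
                       search_space = small_space(), seed = 5)
  expect_equal(m3$cv_report$mean_cv_accuracy,
               m1$cv_report$mean_cv_accuracy, tolerance = 0.1)
})

test_that("predictions are probabilistic, deterministic and schema-checked", {
  ds <- simulate_roi_dataset(n_patients = 8, rois_per_patient = 2, seed = 3)
  model <- train_ensemble(roi_dataset(ds), folds = 4,
                          search_space = small_space(), seed = 5)
  pred <- predict_roi(model, ds)
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  expect_identical(pred, predict_roi(model, ds))
  expect_equal(pred$call, ifelse(pred$probability >= 0.5, "cancer",
                                 "benign"))
  # a confident training point is called correctly
  strongest <- which.max(abs(ds$com - mean(ds$com)))
  expect_equal(pred$call[strongest], ds$label[strongest])
  expect_error(predict_roi(model, ds[, setdiff(names(ds), "com")]),
               "schema mismatch.*com")
})

test_that("patient aggregation rules", {
  expect_equal(aggregate_patient(c("benign", "benign"), "any"), "benign")
  expect_equal(aggregate_patient(c("benign", "benign"), "majority"),
               "benign")
  expect_equal(aggregate_patient(c("benign", "cancer"), "any"), "cancer")
  expect_equal(aggregate_patient(c("benign", "cancer"), "majority"),
               "cancer")  # tie -> cancer
  expect_equal(aggregate_patient(c("benign", "benign", "cancer"), "any"),
               "cancer")
  expect_equal(aggregate_patient(c("benign", "benign", "cancer"),
                                 "majority"), "benign")
  expect_error(aggregate_patient(character(0)), "no ROI calls")
})

test_that("evaluate_calls reproduces the published worked confusions", {
  # biopsy-as-classifier: all 14 lesions biopsy-negative (called benign)
  truth <- rep(c("cancer", "benign"), each = 7)
  ev <- evaluate_calls(rep("benign", 14), truth)
  expect_equal(ev$rounded$accuracy, 50)
  expect_equal(ev$rounded$sensitivity, 0)
  expect_equal(ev$rounded$specificity, 100)
  # patient-level classifier: TP=7 FN=0 TN=5 FP=2 -> 86% accuracy
  calls <- c(rep("cancer", 7), rep("cancer", 2), rep("benign", 5))
  truth2 <- c(rep("cancer", 7), rep("benign", 7))
  ev2 <- evaluate_calls(calls, truth2)
  expect_equal(c(ev2$tp, ev2$fn, ev2$tn, ev2$fp), c(7, 0, 5, 2))
  expect_equal(ev2$rounded$accuracy, 86)
  expect_equal(ev2$rounded$sensitivity, 100)
  expect_equal(ev2$rounded$specificity, 71)
  # perfect predictions
  ev3 <- evaluate_calls(truth, truth)
  expect_equal(unlist(ev3$rounded), c(accuracy = 100, sensitivity = 100,
                                      specificity = 100))
})

test_that("evaluate_calls matches the brute-force oracle on random inputs", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    calls <- sample(c("benign", "cancer"), n, replace = TRUE)
    truth <- sample(c("benign", "cancer"), n, replace = TRUE)
    ev <- evaluate_calls(calls, truth)
    orc <- oracle_metrics(calls, truth)
    expect_equal(ev$tp, orc$tp)
    expect_equal(ev$fp, orc$fp)
    expect_equal(ev$tn, orc$tn)
    expect_equal(ev$fn, orc$fn)
    expect_equal(ev$accuracy, orc$accuracy)
    expect_equal(ev$sensitivity, orc$sensitivity)
    expect_equal(ev$specificity, orc$specificity)
  }
  expect_error(evaluate_calls(stats::setNames(c("benign"), "a"),
                              stats::setNames(c("benign"), "b")),
               "unit ids")
})

test_that("more simulated noise never improves CV accuracy", {
  accs <- vapply(c(5, 120, 400), function(ns) {
    ds <- simulate_roi_dataset(n_patients = 10, rois_per_patient = 3,
                               noise_sd = ns, seed = 19)
    m <- train_ensemble(roi_dataset(ds), folds = 5,
                        search_space = small_space(), seed = 11)
    m$cv_report$mean_cv_accuracy
  }, numeric(1))
  expect_true(all(diff(accs) <= 1e-9))
})
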