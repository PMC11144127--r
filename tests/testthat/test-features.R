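make_curve <- function(y, fps = 30, id = "x", label = "benign") {
  time_intensity_curve(id, label, (seq_along(y) - 1) / fps, y, fps)
}

gamma_curve <- function(t0, alpha, beta, amplitude = 400, baseline = 100,
                        duration = 120, fps = 30, noise_sd = 0, seed = NULL) {
  tt <- seq(0, duration - 1 / fps, by = 1 / fps)
  kp <- kinetic_params(t0 = t0, alpha = alpha, beta = beta,
                       amplitude = amplitude, baseline = baseline,
                       noise_sd = noise_sd)
  make_curve(simulate_kinetic_curve(kp, tt, seed = seed), fps = fps)
}

test_that("flat curve raises 'no perfusion event'", {
  expect_error(preprocess_curve(make_curve(rep(5, 300))),
               "no perfusion event")
  expect_error(preprocess_curve(make_curve(seq(100, 50, length.out = 300))),
               "no perfusion event")
})

test_that("noise-free gamma-variate normalizes to peak 1, baseline 0", {
  nc <- preprocess_curve(gamma_curve(5, 4, 3, amplitude = 500,
                                     baseline = 100))
  expect_equal(max(nc$normalized), 1, tolerance = 1e-9)
  expect_lt(max(abs(nc$normalized[nc$times < 2])), 1e-9)
  expect_equal(nc$baseline, 100, tolerance = 1e-6)
  expect_gt(nc$onset_time, 2)
})

test_that("preprocessing is deterministic for identical noisy input", {
  cv <- gamma_curve(5, 4, 3, noise_sd = 10, seed = 3)
  expect_identical(preprocess_curve(cv), preprocess_curve(cv))
})

test_that("baseline window overlapping onset is an error", {
  expect_error(preprocess_curve(gamma_curve(0.5, 2, 1)), "overlaps")
  expect_error(preprocess_curve(make_curve(1:20)), "too short")
})

test_that("symmetric triangle: com = t_peak, skew 0, upslope = -downslope", {
  fps <- 30; T <- 5
  tt <- seq(0, 2 * T, by = 1 / fps)
  y <- 100 + 300 * pmax(0, 1 - abs(tt - T) / T)
  # baseline window is flat only at the very start; use tiny baseline win
  cfg <- feature_config(smooth_frames = 1L, baseline_seconds = 1 / fps,
                        onset_threshold = 0, onset_min_duration = 0)
  f <- extract_milestones(preprocess_curve(make_curve(y, fps), cfg), cfg)
  expect_equal(f$t_peak, T, tolerance = 1 / fps)
  expect_equal(f$com, T, tolerance = 1e-6)
  expect_equal(f$skew, 0, tolerance = 1e-6)
  expect_equal(f$upslope, -f$downslope, tolerance = 1e-6)
  expect_gt(f$upslope, 0)
})

test_that("gamma-variate milestones match closed forms (worked case)", {
  f <- extract_milestones(preprocess_curve(gamma_curve(5, 4, 3)))
  expect_equal(f$t_peak, 17, tolerance = 1 / 30 + 1e-9)
  expect_equal(f$com, 5 + 5 * 3, tolerance = 0.1)
  expect_equal(f$skew, 2 / sqrt(5), tolerance = 0.01)
  expect_lte(f$downslope, 0)
  expect_gte(f$upslope, 0)
})

test_that("milestones match closed forms and dense-grid oracle on random draws", {
  set.seed(1234)
  for (i in 1:20) {
    a <- runif(1, 2.5, 5); b <- runif(1, 1.5, 3.5); t0 <- runif(1, 3, 8)
    f <- extract_milestones(preprocess_curve(gamma_curve(t0, a, b)))
    orc <- oracle_gamma_milestones(t0, a, b)
    expect_equal(f$t_peak, orc$t_peak, tolerance = 1 / 30 + 1e-9)
    expect_equal(f$com, t0 + (a + 1) * b, tolerance = 0.1)
    expect_equal(f$com, orc$com, tolerance = 0.1)
    expect_equal(f$skew, 2 / sqrt(a + 1), tolerance = 0.01)
    expect_equal(f$skew, orc$skew, tolerance = 0.01)
  }
})

test_that("faster transit (halved beta) strictly reduces t_peak and com", {
  f1 <- extract_milestones(preprocess_curve(gamma_curve(5, 4, 3)))
  f2 <- extract_milestones(preprocess_curve(gamma_curve(5, 4, 1.5)))
  expect_lt(f2$t_peak, f1$t_peak)
  expect_lt(f2$com, f1$com)
})

test_that("time-shift equivariance and amplitude invariance", {
  base <- extract_milestones(preprocess_curve(gamma_curve(4, 4, 2)))
  shifted <- extract_milestones(preprocess_curve(gamma_curve(4 + 3, 4, 2)))
  expect_equal(shifted$t_peak - base$t_peak, 3, tolerance = 1 / 30)
  expect_equal(shifted$com - base$com, 3, tolerance = 0.02)
  expect_equal(shifted$upslope, base$upslope, tolerance = 1e-3)
  expect_equal(shifted$downslope, base$downslope, tolerance = 1e-3)
  expect_equal(shifted$skew, base$skew, tolerance = 1e-3)

  scaled <- extract_milestones(preprocess_curve(
    gamma_curve(4, 4, 2, amplitude = 400 * 5, baseline = 100 * 5)))
  for (m in c("t_peak", "upslope", "downslope", "skew", "com"))
    expect_equal(scaled[[m]], base[[m]], tolerance = 1e-9)
})

test_that("peak at the curve edge is rejected", {
  tt <- seq(0, 10, by = 1 / 30)
  rising <- make_curve(100 + tt * 50)
  cfg <- feature_config(smooth_frames = 1L, baseline_seconds = 1 / 30,
                        onset_threshold = 0, onset_min_duration = 0)
  expect_error(extract_milestones(preprocess_curve(rising, cfg), cfg),
               "no interior maximum")
})

test_that("relative features are deltas and antisymmetric", {
  a <- extract_milestones(preprocess_curve(gamma_curve(5, 4, 3)),
                          recording_id = "rec1")
  b <- extract_milestones(preprocess_curve(gamma_curve(7, 3, 2)),
                          recording_id = "rec1")
  same <- relative_features(a, a)
  for (m in paste0("d_", c("t_peak", "upslope", "downslope", "skew", "com")))
    expect_equal(same[[m]], 0)
  ab <- relative_features(a, b)
  ba <- relative_features(b, a)
  expect_equal(ab$d_t_peak, a$t_peak - b$t_peak)
  expect_equal(ab$d_com, -ba$d_com)
  expect_equal(ab$d_skew, -ba$d_skew)
  c_other <- extract_milestones(preprocess_curve(gamma_curve(5, 4, 3)),
                                recording_id = "rec2")
  expect_error(relative_features(a, c_other), "different recordings")
})
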