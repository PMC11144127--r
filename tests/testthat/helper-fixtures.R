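# Shared fixtures and independent oracles.
#
# Test scenes are desk-scaled (6-12 s instead of the 120 s acquisition
# default) with proportionally faster kinetics, purely to keep the suite
# inside its time budget; the 120 s default is exercised once in
# test-io.R.

# kinetics fast enough that peak + washout fit a ~12 s test recording
fast_kinetics <- function(noise_sd = 5) {
  list(
    normal    = kinetic_params(t0 = 3, alpha = 3, beta = 1.0,
                               amplitude = 250, baseline = 100,
                               noise_sd = noise_sd),
    benign    = kinetic_params(t0 = 4, alpha = 3, beta = 1.2,
                               amplitude = 400, baseline = 100,
                               noise_sd = noise_sd),
    malignant = kinetic_params(t0 = 2.5, alpha = 2, beta = 0.8,
                               amplitude = 450, baseline = 100,
                               noise_sd = noise_sd))
}

small_scene <- function(duration = 12, fps = 30, jitter = NULL,
                        noise_sd = 5, ...) {
  k <- fast_kinetics(noise_sd)
  # ultra-short clips (tracking-only tests): pull arrivals inside the clip
  if (duration < 6)
    for (n in names(k)) k[[n]]$t0 <- min(k[[n]]$t0, duration / 3)
  scene_spec(frame_size = c(64, 64), duration = duration, fps = fps,
             kinetics = k, jitter = jitter, ...)
}

# dense-grid numeric oracle for the gamma-variate milestones: integrates
# the (smoothed-free) normalized curve at dt resolution, independent of
# the implementation under test
oracle_gamma_milestones <- function(t0, alpha, beta, t_max = 120,
                                    dt = 0.001) {
  u <- seq(dt, t_max - t0, by = dt)
  g <- u^alpha * exp(-u / beta)
  w <- g / max(g)
  t <- t0 + u
  com <- sum(t * w) / sum(w)
  v <- sum(w * (t - com)^2) / sum(w)
  skew <- sum(w * (t - com)^3) / sum(w) / v^1.5
  list(t_peak = t0 + alpha * beta, com = com, skew = skew)
}

# brute-force confusion/metric oracle: plain loop over units
oracle_metrics <- function(calls, truth) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(calls)) {
    if (calls[i] == "cancer" && truth[i] == "cancer") tp <- tp + 1L
    if (calls[i] == "cancer" && truth[i] == "benign") fp <- fp + 1L
    if (calls[i] == "benign" && truth[i] == "benign") tn <- tn + 1L
    if (calls[i] == "benign" && truth[i] == "cancer") fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = 100 * (tp + tn) / length(calls),
       sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}

# naive average-rank oracle (independent of base::rank)
oracle_rank <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) {
    less <- sum(x < x[i])
    eq <- sum(x == x[i])
    r[i] <- less + (eq + 1) / 2
  }
  r
}

random_rater_table <- function(seed) {
  simulate_rater_table(rater_model_params(n_raters = 32, n_items = 14,
                                          skill = 0, difficulty = 0,
                                          seed = seed))
}
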