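#' Kinetic parameters of an ICG bolus-transit curve
#'
#' Parameterises the gamma-variate model of indocyanine green (ICG)
#' inflow/washout used by the simulator: after bolus arrival at `t0` the
#' intensity rises as `u^alpha * exp(-u/beta)` (with `u = t - t0`), peak-scaled
#' to `amplitude` above `baseline`, with additive i.i.d. Gaussian sensor noise.
#' The gamma-variate peaks at `u = alpha * beta`, so earlier/faster transits
#' are modelled by reducing `t0` and `alpha * beta`.
#'
#' @param t0 Bolus arrival time (s, >= 0).
#' @param alpha Gamma-variate shape exponent (> 0, unitless).
#' @param beta Gamma-variate time scale (s, > 0).
#' @param amplitude Peak intensity gain above baseline (a.u., >= 0).
#' @param baseline Pre-arrival intensity (a.u., >= 0).
#' @param noise_sd Additive Gaussian noise standard deviation (a.u., >= 0).
#' @return A `kinetic_params` object (named list).
#' @examples
#' kp <- kinetic_params(t0 = 5, alpha = 4, beta = 3, amplitude = 500,
#'                      baseline = 100)
#' @export
kinetic_params <- function(t0 = 10, alpha = 4, beta = 3, amplitude = 400,
                           baseline = 100, noise_sd = 0) {
  assert_number(t0, "t0", lower = 0)
  assert_number(alpha, "alpha", lower = 0, strict_lower = TRUE)
  assert_number(beta, "beta", lower = 0, strict_lower = TRUE)
  assert_number(amplitude, "amplitude", lower = 0)
  assert_number(baseline, "baseline", lower = 0)
  assert_number(noise_sd, "noise_sd", lower = 0)
  structure(list(t0 = t0, alpha = alpha, beta = beta, amplitude = amplitude,
                 baseline = baseline, noise_sd = noise_sd),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "kinetic_params: t0=%g s, alpha=%g, beta=%g s, amplitude=%g, baseline=%g, noise_sd=%g\n",
    x$t0, x$alpha, x$beta, x$amplitude, x$baseline, x$noise_sd))
  cat(sprintf("  noise-free peak at t = t0 + alpha*beta = %g s\n",
              x$t0 + x$alpha * x$beta))
  invisible(x)
}

# Noise-free gamma-variate intensity at times `t` (vectorised).
# Peak-scaled: max over u >= 0 of u^a exp(-u/b) is attained at u = a*b.
gamma_variate <- function(t, params) {
  u <- t - params$t0
  g <- numeric(length(t))
  pos <- u > 0
  if (any(pos)) {
    gmax <- (params$alpha * params$beta)^params$alpha *
      exp(-params$alpha)
    g[pos] <- u[pos]^params$alpha * exp(-u[pos] / params$beta) / gmax
  }
  params$baseline + params$amplitude * g
}

#' Simulate an ICG time-fluorescence curve
#'
#' Generates mean-intensity-vs-time samples for one tissue region:
#' `baseline` before bolus arrival, then a peak-scaled gamma-variate plus
#' i.i.d. Gaussian noise. Negative noisy values are clipped at 0 (intensities
#' are non-negative by definition); clipping only bites when
#' `baseline < ~3 * noise_sd`.
#'
#' @param params A [kinetic_params()] object.
#' @param times Strictly increasing, non-negative sample times (s).
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @return Numeric vector of intensities (a.u.), same length as `times`.
#' @examples
#' tt <- seq(0, 120, by = 1 / 30)
#' y <- simulate_kinetic_curve(kinetic_params(t0 = 5, alpha = 4, beta = 3),
#'                             tt)
#' tt[which.max(y)]  # ~ t0 + alpha*beta = 17 s
#' @export
simulate_kinetic_curve <- function(params, times, seed = NULL) {
  assert_that(inherits(params, "kinetic_params"),
              "`params` must be a kinetic_params object")
  assert_that(is.numeric(times) && length(times) >= 1L && all(is.finite(times)),
              "`times` must be a non-empty finite numeric vector")
  assert_that(all(times >= 0), "`times` must be non-negative")
  assert_that(length(times) < 2L || all(diff(times) > 0),
              "`times` must be strictly increasing")
  y <- gamma_variate(times, params)
  if (params$noise_sd > 0) {
    y <- y + with_seed(seed, stats::rnorm(length(times), 0, params$noise_sd))
    y <- pmax(y, 0)
  }
  y
}
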