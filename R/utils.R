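# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fp <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop_fp(fmt, ...)
  invisible(TRUE)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  assert_that(is.numeric(x) && length(x) == 1L && is.finite(x),
              "`%s` must be a single finite number", name)
  if (strict_lower) {
    assert_that(x > lower, "`%s` must be > %g (got %g)", name, lower, x)
  } else {
    assert_that(x >= lower, "`%s` must be >= %g (got %g)", name, lower, x)
  }
  assert_that(x <= upper, "`%s` must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package funnel through this.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic fan-out of one global seed to per-stage seeds: a small
# string hash keeps every stage independently re-runnable (kept < 2^31).
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 7919 + h) %% 2147483587)
}

# Round half away from zero, as clinical report tables (SPSS) do;
# base::round() uses banker's rounding (3.125 -> 3.12, not 3.13).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
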