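# Small numeric helpers shared across modules.

#' Truncated normal sampler
#'
#' Draws from a normal distribution restricted to `[lower, upper]` by
#' inverse-CDF sampling. Used for bounded ground-truth quantities (fiber
#' angles in \[0, 90\] degrees, strictly positive moduli and ratios) where
#' only a mean and standard deviation are specified.
#'
#' @param n number of draws.
#' @param mean,sd location and scale of the parent normal; `sd = 0` returns
#'   the mean (clipped to the bounds) exactly.
#' @param lower,upper truncation bounds.
#' @return numeric vector of length `n`.
#' @export
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd >= 0, lower < upper)
  if (sd == 0) {
    return(rep(min(max(mean, lower), upper), n))
  }
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Mean of a truncated normal
#'
#' Closed-form expectation of a normal restricted to `[lower, upper]`.
#' @inheritParams rtruncnorm
#' @return scalar expectation.
#' @keywords internal
truncnorm_mean <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(min(max(mean, lower), upper))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

#' Round half away from zero
#'
#' Report-table rounding convention: ties are rounded away from zero
#' (so -58.55 -> -58.6), unlike [base::round()]'s banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-12) / m
}

# Deterministic per-stage child seeds: a single run seed is fanned out by a
# fixed counter scheme so individual stages can be rerun in isolation.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + 104729 * index) %% 2147483629)
}

# Expectation of a function of a truncated-normal variable, by quadrature.
truncnorm_efun <- function(f, mean, sd, lower, upper) {
  if (sd == 0) return(f(min(max(mean, lower), upper)))
  z <- pnorm(upper, mean, sd) - pnorm(lower, mean, sd)
  integrate(function(x) f(x) * dnorm(x, mean, sd) / z,
            lower = max(lower, mean - 8 * sd),
            upper = min(upper, mean + 8 * sd))$value
}

`%||%` <- function(a, b) if (is.null(a)) b else a
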