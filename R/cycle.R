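#' Parametric cell-cycle time distributions
#'
#' Constructs a validated cell-cycle time law used by all simulators.
#' Three families are supported:
#'
#' * `"exponential"` — the memoryless (Markovian) law, mean `mean_cycle`;
#'   requires `shape = 1` and `t_min = 0`.
#' * `"shifted_gamma"` — a refractory minimum period `t_min` plus a
#'   gamma-distributed remainder: `t_min + Gamma(shape, scale)` with
#'   `scale = (mean_cycle - t_min) / shape`, so the mean is exactly
#'   `mean_cycle`. Large shapes give narrow, clock-like cycles.
#' * `"deterministic"` — the `shape -> Inf` limit: every cycle equals
#'   `mean_cycle` exactly.
#'
#' All durations are in days. The implied division rate is reported in
#' /week (`7 / mean_cycle`).
#'
#' @param family one of `"exponential"`, `"shifted_gamma"`, `"deterministic"`
#' @param mean_cycle mean cell-cycle period (days, > 0)
#' @param shape gamma shape parameter (dimensionless, > 0); ignored for
#'   deterministic, must be 1 for exponential
#' @param t_min refractory minimum cycle time (days, `0 <= t_min < mean_cycle`);
#'   must be 0 for exponential
#' @return an object of class `cycle_distribution` with fields `family`,
#'   `mean_cycle`, `shape`, `t_min` and `rate_per_week`
#' @examples
#' cyc <- cycle_distribution("shifted_gamma", mean_cycle = 7 / 2.9,
#'                           shape = 8, t_min = 0.5)
#' cyc$rate_per_week  # 2.9
#' @export
cycle_distribution <- function(family = c("exponential", "shifted_gamma",
                                          "deterministic"),
                               mean_cycle, shape = 1, t_min = 0) {
  family <- match.arg(family)
  if (!is.numeric(mean_cycle) || length(mean_cycle) != 1 || mean_cycle <= 0)
    abort_invalid("`mean_cycle` must be a single positive duration in days.")
  if (!is.numeric(shape) || length(shape) != 1 || shape <= 0)
    abort_invalid("`shape` must be a single positive real.")
  if (!is.numeric(t_min) || length(t_min) != 1 || t_min < 0)
    abort_invalid("`t_min` must be a non-negative duration in days.")
  if (t_min >= mean_cycle)
    abort_invalid(sprintf(
      "`t_min` (%g d) must be strictly below `mean_cycle` (%g d).",
      t_min, mean_cycle))
  if (family == "exponential" && (shape != 1 || t_min != 0))
    abort_invalid("exponential cycles require `shape = 1` and `t_min = 0`.")
  if (family == "deterministic") shape <- Inf
  structure(
    list(family = family, mean_cycle = mean_cycle, shape = shape,
         t_min = t_min,
         rate_per_week = mean_cycle_to_rate(mean_cycle)),
    class = "cycle_distribution")
}

#' @export
print.cycle_distribution <- function(x, ...) {
  cat(sprintf(
    "<cycle_distribution> %s: mean %.3g d (rate %.3g /week), shape %s, t_min %.3g d\n",
    x$family, x$mean_cycle, x$rate_per_week, format(x$shape), x$t_min))
  invisible(x)
}

is_cycle_distribution <- function(x) inherits(x, "cycle_distribution")

## Integer code handed to the C++ engine.
cycle_family_code <- function(dist) {
  switch(dist$family, exponential = 0L, shifted_gamma = 1L, deterministic = 2L)
}

#' Coefficient of variation of a cycle distribution
#' @param dist a [cycle_distribution()]
#' @return the analytic CV of the cycle time
#' @export
cycle_cv <- function(dist) {
  switch(dist$family,
    exponential = 1,
    deterministic = 0,
    shifted_gamma = {
      s <- (dist$mean_cycle - dist$t_min) / sqrt(dist$shape)
      s / dist$mean_cycle
    })
}

## Cumulative distribution function of the cycle time, used by the
## residual-life oracle and by tests.
cycle_cdf <- function(dist, q) {
  switch(dist$family,
    exponential = stats::pexp(q, rate = 1 / dist$mean_cycle),
    deterministic = as.numeric(q >= dist$mean_cycle),
    shifted_gamma = pgamma(pmax(q - dist$t_min, 0), shape = dist$shape,
                           scale = (dist$mean_cycle - dist$t_min) / dist$shape))
}

#' Sample cell-cycle times
#'
#' Draws `n` independent cycle periods from a cycle-time law. Every sample
#' is at least `t_min`; the sample mean converges to `mean_cycle`.
#'
#' @param dist a [cycle_distribution()]
#' @param n number of samples (>= 1)
#' @param seed optional integer seed; if `NULL` the current RNG stream is used
#' @return numeric vector of durations (days)
#' @export
sample_cycle_times <- function(dist, n, seed = NULL) {
  stopifnot(is_cycle_distribution(dist))
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    abort_invalid("`n` must be a positive count.")
  with_seed(seed, switch(dist$family,
    exponential = rexp(n, rate = 1 / dist$mean_cycle),
    deterministic = rep(dist$mean_cycle, n),
    shifted_gamma = dist$t_min +
      rgamma(n, shape = dist$shape,
             scale = (dist$mean_cycle - dist$t_min) / dist$shape)))
}

#' Sample the time to first division of a cell observed mid-cycle
#'
#' A labeling pulse or chase start catches cells at a uniformly random
#' point of their cycle. The time remaining until their first division
#' then follows the stationary-renewal residual-life law with density
#' `(1 - F(u)) / mean_cycle`. Sampling uses the classical construction
#' `U * X*` where `X*` is a length-biased cycle draw and `U` is uniform;
#' for the shifted gamma the length-biased draw is the mixture
#' `t_min + Gamma(shape + B, scale)` with
#' `B ~ Bernoulli((mean_cycle - t_min) / mean_cycle)`.
#'
#' @inheritParams sample_cycle_times
#' @return numeric vector of residual times (days)
#' @export
sample_initial_phase <- function(dist, n = 1, seed = NULL) {
  stopifnot(is_cycle_distribution(dist))
  with_seed(seed, {
    x_star <- switch(dist$family,
      exponential = rgamma(n, shape = 2, scale = dist$mean_cycle),
      deterministic = rep(dist$mean_cycle, n),
      shifted_gamma = {
        sc <- (dist$mean_cycle - dist$t_min) / dist$shape
        b <- rbinom(n, 1, (dist$mean_cycle - dist$t_min) / dist$mean_cycle)
        dist$t_min + rgamma(n, shape = dist$shape + b, scale = sc)
      })
    runif(n) * x_star
  })
}
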