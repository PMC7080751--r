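#' Single-progenitor model parameters
#'
#' The single-progenitor (SP) model describes a basal layer maintained by
#' one population of equivalent proliferating cells. A progenitor divides
#' after a cycle-time draw and the daughter pair is PP with probability
#' `r`, PD with `1 - 2r`, and DD with `r` (P = progenitor, D =
#' differentiating basal cell). Differentiating cells leave the basal
#' layer (stratify) after an exponential wait at rate `Gamma`; suprabasal
#' cells are optionally shed at rate `mu`. In homeostasis the basal flux
#' balance ties the stratification rate to the progenitor fraction `rho`:
#' `Gamma = rho * lambda / (1 - rho)`; the constructor enforces this
#' identity unless `Gamma` is supplied explicitly (non-homeostatic mode).
#'
#' @param lambda division rate (/week, > 0)
#' @param r probability of a symmetric division outcome (PP or DD), in
#'   `[0, 0.5]`
#' @param rho progenitor fraction of basal cells, in `(0, 1]`; `rho = 1`
#'   means every basal cell is a progenitor (instant stratification)
#' @param cycle a [cycle_distribution()]; defaults to the exponential law
#'   with mean `7 / lambda` days. Its mean must equal `7 / lambda`.
#' @param Gamma stratification rate (/week); default `NULL` derives the
#'   homeostatic value `rho * lambda / (1 - rho)`
#' @param mu suprabasal shedding rate (/week); default `NULL` disables
#'   shedding so suprabasal counts accumulate
#' @return an object of class `sp_params`
#' @examples
#' p <- sp_params(lambda = 2.9, r = 0.10, rho = 0.65,
#'                cycle = cycle_distribution("shifted_gamma", 7 / 2.9, 8, 0.5))
#' p$Gamma  # 5.386 /week
#' @export
sp_params <- function(lambda, r, rho, cycle = NULL, Gamma = NULL, mu = NULL) {
  if (!is.numeric(lambda) || lambda <= 0)
    abort_invalid("`lambda` must be a positive rate in /week.")
  if (!is.numeric(r) || r < 0 || r > 0.5)
    abort_invalid("`r` must lie in [0, 0.5] (1 - 2r must be a probability).")
  if (!is.numeric(rho) || rho <= 0 || rho > 1)
    abort_invalid("`rho` must lie in (0, 1].")
  if (is.null(cycle))
    cycle <- cycle_distribution("exponential", mean_cycle = rate_to_mean_cycle(lambda))
  stopifnot(is_cycle_distribution(cycle))
  if (abs(cycle$mean_cycle - rate_to_mean_cycle(lambda)) >
        1e-9 * rate_to_mean_cycle(lambda))
    abort_invalid("`cycle$mean_cycle` must equal 7 / lambda days.")
  if (is.null(Gamma)) {
    Gamma <- if (rho == 1) Inf else homeostatic_stratification_rate(rho, lambda)
  } else if (!is.numeric(Gamma) || Gamma <= 0) {
    abort_invalid("`Gamma` must be a positive rate in /week.")
  }
  if (!is.null(mu) && (!is.numeric(mu) || mu <= 0))
    abort_invalid("`mu` must be NULL or a positive rate in /week.")
  structure(
    list(lambda = lambda, r = r, rho = rho, Gamma = Gamma, mu = mu,
         cycle = cycle),
    class = "sp_params")
}

#' @export
print.sp_params <- function(x, ...) {
  cat(sprintf(
    "<sp_params> lambda %.3g /week, r %.3g, rho %.3g, Gamma %.3g /week%s\n",
    x$lambda, x$r, x$rho, x$Gamma,
    if (is.null(x$mu)) "" else sprintf(", mu %.3g /week", x$mu)))
  print(x$cycle)
  invisible(x)
}

is_sp_params <- function(x) inherits(x, "sp_params")

#' Homeostatic stratification rate
#'
#' In homeostasis the rate at which differentiating cells leave the basal
#' layer must balance the production of differentiating daughters, which
#' fixes `Gamma = rho * lambda / (1 - rho)`.
#'
#' @param rho progenitor fraction of basal cells, in (0, 1)
#' @param lambda division rate (/week)
#' @return stratification rate Gamma (/week)
#' @examples
#' homeostatic_stratification_rate(0.65, 2.9)  # 5.39
#' @export
homeostatic_stratification_rate <- function(rho, lambda) {
  if (!is.numeric(rho) || any(rho <= 0) || any(rho >= 1))
    abort_invalid("`rho` must lie strictly inside (0, 1).")
  if (!is.numeric(lambda) || any(lambda <= 0))
    abort_invalid("`lambda` must be positive.")
  rho * lambda / (1 - rho)
}

#' Two-population hierarchy parameters (SC-CP and 2xSC models)
#'
#' Describes basal-layer maintenance by two proliferating populations.
#' Each population has its own division rate, cycle law, and daughter-pair
#' fate probabilities over the six unordered pairs AA, AB, AD, BB, BD, DD
#' (A = type 1, B = type 2, D = differentiating basal cell).
#'
#' Two named constructions cover the competing models:
#' * `two_sc_params()` — two independent stem-cell populations (2xSC), each
#'   behaving as a balanced single-progenitor population with its own rate.
#' * `sc_cp_params()` — a stem-cell/committed-progenitor hierarchy (SC-CP):
#'   slow stems (type A) renew and feed progenitors (type B) whose fate is
#'   skewed toward differentiation by an imbalance `delta`, so the
#'   progenitor pool needs constant stem output.
#'
#' @param rates division rates (/week), length 2 (A, B)
#' @param fates 2 x 6 matrix of daughter-pair probabilities, rows = dividing
#'   type, columns = AA, AB, AD, BB, BD, DD; each row sums to 1
#' @param fractions fractions of each proliferating type at labeling
#'   (length 2, sums to 1)
#' @param rho proliferating fraction of basal cells
#' @param cycles list of two [cycle_distribution()] objects; default
#'   exponential at each rate
#' @param Gamma stratification rate (/week); default balances total basal
#'   flux: `Gamma = rho * <lambda_out> / (1 - rho)` where `<lambda_out>` is
#'   the fraction-weighted rate of D production per proliferating cell
#' @return an object of class `hierarchy_params`
#' @export
hierarchy_params <- function(rates, fates, fractions, rho, cycles = NULL,
                             Gamma = NULL) {
  stopifnot(length(rates) == 2, all(rates > 0),
            is.matrix(fates), nrow(fates) == 2, ncol(fates) == 6,
            length(fractions) == 2)
  if (any(fates < 0) || any(abs(rowSums(fates) - 1) > 1e-8))
    abort_invalid("each fate row must be a probability vector summing to 1.")
  if (abs(sum(fractions) - 1) > 1e-8 || any(fractions < 0))
    abort_invalid("`fractions` must be non-negative and sum to 1.")
  if (rho <= 0 || rho > 1) abort_invalid("`rho` must lie in (0, 1].")
  if (is.null(cycles))
    cycles <- lapply(rates, function(l)
      cycle_distribution("exponential", rate_to_mean_cycle(l)))
  stopifnot(length(cycles) == 2, all(vapply(cycles, is_cycle_distribution,
                                            logical(1))))
  for (k in 1:2)
    if (abs(cycles[[k]]$mean_cycle - rate_to_mean_cycle(rates[k])) >
          1e-9 * rate_to_mean_cycle(rates[k]))
      abort_invalid("each cycle mean must equal 7 / rate days.")
  if (is.null(Gamma)) {
    # mean number of D daughters per division, per type: AD + BD + 2 DD
    d_out <- fates[, 3] + fates[, 5] + 2 * fates[, 6]
    lambda_out <- sum(fractions * rates * d_out)
    Gamma <- if (rho == 1) Inf else rho * lambda_out / (1 - rho)
  }
  structure(
    list(rates = rates, fates = fates, fractions = fractions, rho = rho,
         Gamma = Gamma, cycles = cycles),
    class = "hierarchy_params")
}

#' @rdname hierarchy_params
#' @param lambda_fast division rate of the faster population (/week)
#' @param rate_ratio fold slow-down of the stem population (default 4)
#' @param r_each symmetric-division probability within each population
#' @param stem_fraction fraction of proliferating cells that are stems
#' @export
two_sc_params <- function(lambda_fast, rate_ratio = 4, r_each = 0.1,
                          stem_fraction = 0.3, rho = 1, cycles = NULL) {
  fates <- rbind(c(r_each, 0, 1 - 2 * r_each, 0, 0, r_each),   # A divides
                 c(0, 0, 0, r_each, 1 - 2 * r_each, r_each))   # B divides
  hierarchy_params(rates = c(lambda_fast / rate_ratio, lambda_fast),
                   fates = fates,
                   fractions = c(stem_fraction, 1 - stem_fraction),
                   rho = rho, cycles = cycles)
}

#' @rdname hierarchy_params
#' @param p_ss probability a stem division yields two stems
#' @param p_scp probability a stem division yields a stem and a progenitor
#' @param delta committed-progenitor fate imbalance toward differentiation:
#'   progenitor fates are BB with `(1 - delta) / 2 - delta_adj`, BD with
#'   `2 * delta_adj`, DD with `(1 - delta) / 2 + ...`; concretely
#'   BB = (1 - delta) * r_cp, DD = (1 + delta) * r_cp, BD = 1 - 2 * r_cp
#' @param r_cp committed-progenitor symmetric-outcome scale
#' @export
sc_cp_params <- function(lambda_fast, rate_ratio = 4, stem_fraction = 0.12,
                         p_ss = 0.1, p_scp = 0.8, delta = 0.1, r_cp = 0.2,
                         rho = 1, cycles = NULL) {
  # stem fates: AA, AB (stem + progenitor), AD, BB, BD, DD
  p_sd <- 1 - p_ss - p_scp
  stopifnot(p_sd >= 0)
  fates <- rbind(c(p_ss, p_scp, p_sd, 0, 0, 0),
                 c(0, 0, 0, (1 - delta) * r_cp, 1 - 2 * r_cp,
                   (1 + delta) * r_cp))
  hierarchy_params(rates = c(lambda_fast / rate_ratio, lambda_fast),
                   fates = fates,
                   fractions = c(stem_fraction, 1 - stem_fraction),
                   rho = rho, cycles = cycles)
}

is_hierarchy_params <- function(x) inherits(x, "hierarchy_params")

## Flatten either parameter object into the argument set of the C++ engine.
engine_args <- function(params) {
  if (is_sp_params(params)) {
    fate <- matrix(c(params$r, 0, 1 - 2 * params$r, 0, 0, params$r),
                   nrow = 1)
    list(fate = fate,
         fam = cycle_family_code(params$cycle),
         mean_cc = params$cycle$mean_cycle,
         shape = if (is.finite(params$cycle$shape)) params$cycle$shape else 1,
         tmin = params$cycle$t_min,
         gamma_day = params$Gamma / DAYS_PER_WEEK,
         mu_day = if (is.null(params$mu)) -1 else params$mu / DAYS_PER_WEEK,
         rho = params$rho,
         frac = 1)
  } else if (is_hierarchy_params(params)) {
    list(fate = params$fates,
         fam = vapply(params$cycles, cycle_family_code, integer(1)),
         mean_cc = vapply(params$cycles, function(c) c$mean_cycle, double(1)),
         shape = vapply(params$cycles, function(c)
           if (is.finite(c$shape)) c$shape else 1, double(1)),
         tmin = vapply(params$cycles, function(c) c$t_min, double(1)),
         gamma_day = params$Gamma / DAYS_PER_WEEK,
         mu_day = -1,
         rho = params$rho,
         frac = params$fractions)
  } else {
    abort_invalid("`params` must be an sp_params or hierarchy_params object.")
  }
}
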