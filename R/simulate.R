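#' Simulate a single clone trajectory
#'
#' Runs the exact event-driven simulation of one labeled clone under the
#' single-progenitor model and records its composition at the requested
#' times. A progenitor divides after a draw from the cycle law (its first
#' division from the stationary-renewal residual law, since labeling
#' catches cells mid-cycle); the daughter pair is PP/PD/DD with
#' probabilities `r`, `1 - 2r`, `r`. A differentiating basal cell
#' stratifies after an exponential wait at rate `Gamma`; suprabasal cells
#' are shed at rate `mu` when configured, otherwise they accumulate.
#'
#' @param params an [sp_params()] object
#' @param initial `"progenitor"` starts the clone from a proliferating
#'   cell; `"basal_representative"` starts from a progenitor with
#'   probability `rho`, else a differentiating basal cell
#' @param record_times sorted, non-negative times (days)
#' @param seed optional integer seed
#' @return a tibble with columns `time`, `n_progenitor`, `n_diff_basal`,
#'   `n_basal`, `n_suprabasal`
#' @export
simulate_clone <- function(params, initial = c("progenitor",
                                               "basal_representative"),
                           record_times, seed = NULL) {
  initial <- match.arg(initial)
  check_record_times(record_times)
  stopifnot(is_sp_params(params))
  out <- with_seed(seed, run_engine_sizes(params, 1L, record_times, initial))
  tibble::tibble(
    time = record_times,
    n_progenitor = as.integer(out$n_progenitor[1, ]),
    n_diff_basal = as.integer(out$n_diff_basal[1, ]),
    n_basal = as.integer(out$n_progenitor[1, ] + out$n_diff_basal[1, ]),
    n_suprabasal = as.integer(out$n_suprabasal[1, ]))
}

#' Simulate many clones and return per-clone records
#'
#' Like [simulate_clone()] but for an ensemble, returning one row per clone
#' and record time. Accepts single-progenitor or two-population hierarchy
#' parameters.
#'
#' @inheritParams simulate_clone
#' @param n_clones number of independent clones (>= 1)
#' @return a tibble with columns `clone_id`, `time`, `n_progenitor`,
#'   `n_diff_basal`, `n_basal`, `n_suprabasal`
#' @export
simulate_clones <- function(params, n_clones, record_times,
                            initial = c("progenitor", "basal_representative"),
                            seed = NULL) {
  initial <- match.arg(initial)
  check_record_times(record_times)
  stopifnot(n_clones >= 1)
  out <- with_seed(seed,
                   run_engine_sizes(params, as.integer(n_clones),
                                    record_times, initial))
  T <- length(record_times)
  tibble::tibble(
    clone_id = rep(seq_len(n_clones), times = T),
    time = rep(record_times, each = n_clones),
    n_progenitor = as.integer(out$n_progenitor),
    n_diff_basal = as.integer(out$n_diff_basal),
    n_basal = as.integer(out$n_progenitor + out$n_diff_basal),
    n_suprabasal = as.integer(out$n_suprabasal))
}

run_engine_sizes <- function(params, n_clones, record_times, initial) {
  a <- engine_args(params)
  cpp_simulate_sizes(
    n_clones, as.numeric(record_times), a$fate, as.integer(a$fam),
    as.numeric(a$mean_cc), as.numeric(a$shape), as.numeric(a$tmin),
    a$gamma_day, a$mu_day, a$rho, as.numeric(a$frac),
    if (initial == "progenitor") 0L else 1L)
}

check_record_times <- function(record_times) {
  if (length(record_times) == 0)
    abort_invalid("`record_times` must contain at least one time.")
  if (any(record_times < 0) || is.unsorted(record_times))
    abort_invalid("`record_times` must be sorted and non-negative.")
}

#' Simulate clone-size distributions at each record time
#'
#' Simulates an ensemble of clones under one of the competing models and
#' returns, for each record time, the distribution of basal clone sizes
#' conditioned on survival (at least one basal cell), with the surviving
#' fraction reported. Sizes `>= max_size` are pooled into a final open bin.
#'
#' @param model `"SP"`, `"SCCP"` or `"TwoSC"`; must match the class of
#'   `params` ([sp_params()] for SP, [hierarchy_params()] otherwise)
#' @inheritParams simulate_clones
#' @param max_size pooling bound K: bins are basal sizes `1 ... K-1` and `K+`
#' @return a `clone_size_distribution` tibble with columns `time`, `size`
#'   (bin lower edge; the last bin `size == max_size` is the pooled tail),
#'   `count`, `prob`, `n_surviving`, `n_simulated`, `surviving_fraction`
#' @export
simulate_clone_ensemble <- function(model = c("SP", "SCCP", "TwoSC"), params,
                                    n_clones, record_times, max_size = 12,
                                    initial = c("progenitor",
                                                "basal_representative"),
                                    seed = NULL) {
  model <- match.arg(model)
  initial <- match.arg(initial)
  check_record_times(record_times)
  stopifnot(n_clones >= 1)
  ok <- (model == "SP" && is_sp_params(params)) ||
    (model %in% c("SCCP", "TwoSC") && is_hierarchy_params(params))
  if (!ok)
    abort_invalid(sprintf("model '%s' does not match the class of `params`.",
                          model))
  out <- with_seed(seed, run_engine_sizes(params, as.integer(n_clones),
                                          record_times, initial))
  basal <- out$n_progenitor + out$n_diff_basal
  dists <- purrr::map(seq_along(record_times), function(j) {
    sizes_to_distribution(basal[, j], record_times[j], max_size)
  })
  new_clone_size_distribution(dplyr::bind_rows(dists))
}

## Turn a vector of basal sizes (one per simulated/observed clone,
## extinct clones as 0) into one time point's binned distribution.
sizes_to_distribution <- function(sizes, time, max_size) {
  n_total <- length(sizes)
  surv <- sizes[sizes >= 1]
  counts <- tabulate(pmin(surv, max_size), nbins = max_size)
  n_surv <- length(surv)
  tibble::tibble(
    time = time,
    size = seq_len(max_size),
    count = counts,
    prob = if (n_surv > 0) counts / n_surv else rep(NA_real_, max_size),
    n_surviving = n_surv,
    n_simulated = n_total,
    surviving_fraction = n_surv / n_total)
}

new_clone_size_distribution <- function(df) {
  class(df) <- c("clone_size_distribution", class(df))
  df
}

#' @export
print.clone_size_distribution <- function(x, ...) {
  cat(sprintf("<clone_size_distribution> %d time point(s), pooled tail at %d+\n",
              length(unique(x$time)), max(x$size)))
  NextMethod()
}

#' Simulate H2B-GFP label dilution in a homeostatic basal population
#'
#' Starts a pooled homeostatic basal population (a fraction `rho` of
#' progenitors at stationary cycle phase, the rest differentiating cells)
#' in which every cell carries a lognormal initial label intensity. Every
#' division halves the parent's intensity into both daughters (optionally
#' an asymmetric beta-distributed partition); differentiating basal cells
#' keep their intensity until stratification removes them from the
#' observed pool. At each chase time the intensities of all basal cells
#' then alive are recorded, multiplied by lognormal measurement noise.
#'
#' With `rho = 1` there is no differentiating basal compartment: every
#' differentiating daughter stratifies instantly and the observed pool is
#' progenitors only.
#'
#' @param params an [sp_params()] or [hierarchy_params()] object
#' @param chase_times chase times in days; must include 0
#' @param n_initial_cells basal cells at chase start (>= 1)
#' @param init_intensity list with `mean` and `cv` of the lognormal initial
#'   intensity law (arbitrary fluorescence units)
#' @param measurement_noise_cv CV of multiplicative lognormal measurement
#'   noise (>= 0)
#' @param partition_alpha if > 0, label is split between daughters as
#'   `Beta(alpha, alpha)` instead of exactly in half
#' @param seed optional integer seed
#' @return an intensity-table tibble with columns `mouse_id`, `time_days`,
#'   `fov_id`, `cell_id`, `intensity`, `is_leukocyte`
#' @export
simulate_dilution <- function(params, chase_times, n_initial_cells,
                              init_intensity = list(mean = 1, cv = 0.3),
                              measurement_noise_cv = 0,
                              partition_alpha = 0, seed = NULL) {
  if (!any(chase_times == 0))
    abort_invalid("`chase_times` must include 0 (the chase start).")
  if (is.unsorted(chase_times) || any(chase_times < 0))
    abort_invalid("`chase_times` must be sorted and non-negative.")
  if (n_initial_cells < 1)
    abort_invalid("`n_initial_cells` must be >= 1.")
  if (measurement_noise_cv < 0)
    abort_invalid("`measurement_noise_cv` must be non-negative.")
  a <- engine_args(params)
  with_seed(seed, {
    i0 <- rlnorm_mean_cv(n_initial_cells, init_intensity$mean,
                         init_intensity$cv)
    raw <- cpp_simulate_dilution(
      i0, as.numeric(chase_times), a$fate, as.integer(a$fam),
      as.numeric(a$mean_cc), as.numeric(a$shape), as.numeric(a$tmin),
      a$gamma_day, a$rho, as.numeric(a$frac), partition_alpha)
    purrr::map2_dfr(raw, chase_times, function(v, tt) {
      v <- as.numeric(v)
      if (measurement_noise_cv > 0 && length(v) > 0)
        v <- v * rlnorm_mean_cv(length(v), 1, measurement_noise_cv)
      tibble::tibble(mouse_id = "sim", time_days = tt,
                     fov_id = "sim", cell_id = seq_along(v),
                     intensity = v, is_leukocyte = FALSE)
    })
  })
}

## Lognormal draws parameterized by arithmetic mean and CV.
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}
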