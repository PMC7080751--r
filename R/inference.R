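#' Bin observed clone sizes
#'
#' Converts a clone table into per-time-point clone-size distributions:
#' clones with no basal cell are excluded (a clone "survives" while it
#' retains at least one basal cell), and sizes at or above `max_size` are
#' pooled into an open tail bin.
#'
#' @param clone_table a tibble with at least `time_days` and `n_basal`
#' @param max_size pooling bound K: bins are sizes `1 ... K-1` and `K+`
#' @return an `observed_clone_distribution` tibble with columns `time`,
#'   `size`, `count`, `prob`, `n_clones`
#' @export
bin_clone_sizes <- function(clone_table, max_size = 12) {
  if (nrow(clone_table) == 0) abort_invalid("empty clone table.")
  stopifnot(all(c("time_days", "n_basal") %in% names(clone_table)))
  out <- clone_table |>
    dplyr::filter(.data$n_basal >= 1) |>
    dplyr::reframe({
      counts <- tabulate(pmin(.data$n_basal, max_size), nbins = max_size)
      tibble::tibble(size = seq_len(max_size), count = counts,
                     prob = counts / sum(counts), n_clones = sum(counts))
    }, .by = "time_days") |>
    dplyr::rename(time = "time_days") |>
    dplyr::arrange(.data$time, .data$size)
  class(out) <- c("observed_clone_distribution", class(out))
  out
}

#' Multinomial log-likelihood of observed clone sizes under a simulation
#'
#' Computes `sum(n_b * log(p_b))` over matching bins, where simulated
#' probabilities are floored at `floor` (default `1 / (2 * n_simulated)`)
#' and renormalized, so observed counts in unsimulated bins stay finite.
#'
#' @param obs an `observed_clone_distribution` (one or more times)
#' @param sim a `clone_size_distribution` from [simulate_clone_ensemble()]
#'   with the same times and bin scheme
#' @param floor probability floor; `NULL` uses `1 / (2 * n_simulated)`
#' @return the total log-likelihood (summed over time points)
#' @export
clone_size_loglik <- function(obs, sim, floor = NULL) {
  times <- unique(obs$time)
  if (!setequal(times, unique(sim$time)) ||
      max(obs$size) != max(sim$size))
    abort_invalid("observed and simulated distributions must share times and bins.")
  total <- 0
  for (tt in times) {
    o <- obs[obs$time == tt, ]
    s <- sim[sim$time == tt, ]
    o <- o[order(o$size), ]; s <- s[order(s$size), ]
    fl <- floor %||% (1 / (2 * s$n_simulated[1]))
    p <- pmax(s$prob, fl)
    p <- p / sum(p)
    if (any(o$count > 0 & s$prob == 0))
      rlang::warn("observed counts fall in bins with zero simulated probability; the floor keeps the likelihood finite.")
    total <- total + sum(o$count * log(p))
  }
  total
}

## Fast internal path: binned survival-conditioned probabilities for one
## parameter set, straight from the engine matrices.
sim_binned <- function(params, times, max_size, n_sim, initial, seed) {
  out <- with_seed(seed, run_engine_sizes(params, n_sim, times, initial))
  basal <- out$n_progenitor + out$n_diff_basal
  probs <- matrix(0, max_size, length(times))
  surv <- numeric(length(times))
  for (j in seq_along(times)) {
    sz <- basal[, j]
    sz <- sz[sz >= 1]
    cnt <- tabulate(pmin(sz, max_size), nbins = max_size)
    probs[, j] <- cnt / length(sz)
    surv[j] <- length(sz) / n_sim
  }
  list(probs = probs, surviving_fraction = surv)
}

#' Maximum-likelihood grid search for progenitor parameters
#'
#' Infers the symmetric-division probability `r` and the progenitor
#' fraction `rho` from clone-size distributions, with the division rate
#' and cycle-time law fixed externally (from the label-dilution analysis —
#' the constraint that removes the degeneracy between turnover rate and
#' division symmetry). For every grid point the stratification rate is
#' eliminated by the homeostatic identity `Gamma = rho * lambda / (1 -
#' rho)`, an ensemble of clones is simulated with common random numbers
#' (the same substream seed at every grid point, smoothing the Monte-Carlo
#' likelihood surface), and the multinomial log-likelihood of the observed
#' distributions is summed over time points. Profile-likelihood 95%
#' confidence intervals use the likelihood-ratio threshold.
#'
#' @param obs an `observed_clone_distribution` from [bin_clone_sizes()]
#' @param lambda fixed division rate (/week)
#' @param cycle fixed [cycle_distribution()] (its mean must be `7/lambda`)
#' @param r_grid,rho_grid grid axes; points with `r > 0.5` or `rho`
#'   outside (0, 1) are skipped with a warning
#' @param n_sim simulated clones per grid point
#' @param initial initial-cell mode of the simulated clones
#' @param Gamma optional fixed stratification rate (/week) for
#'   non-homeostatic fits; default derives it from `rho` at each point
#' @param seed optional integer seed (controls the common random numbers)
#' @return an object of class `sp_fit`: parameter estimates, the
#'   log-likelihood surface, profile CIs, and goodness-of-fit statistics
#' @export
mle_grid_search <- function(obs, lambda, cycle,
                            r_grid = seq(0.01, 0.5, by = 0.01),
                            rho_grid = seq(0.05, 0.95, by = 0.05),
                            n_sim = 20000,
                            initial = c("progenitor", "basal_representative"),
                            Gamma = NULL, seed = NULL) {
  initial <- match.arg(initial)
  if (length(r_grid) == 0 || length(rho_grid) == 0)
    abort_invalid("parameter grids must be non-empty.")
  bad_r <- r_grid[r_grid > 0.5 | r_grid < 0]
  bad_rho <- rho_grid[rho_grid <= 0 | rho_grid >= 1]
  if (length(bad_r) > 0 || length(bad_rho) > 0)
    rlang::warn("grid points with r outside [0, 0.5] or rho outside (0, 1) are skipped.")
  r_grid <- r_grid[r_grid <= 0.5 & r_grid >= 0]
  rho_grid <- rho_grid[rho_grid > 0 & rho_grid < 1]
  if (length(r_grid) == 0 || length(rho_grid) == 0)
    abort_invalid("no valid grid points remain.")
  times <- sort(unique(obs$time))
  max_size <- max(obs$size)
  crn_seed <- derive_seed(seed %||% 0, "mle_grid")
  surface <- tidyr::expand_grid(r = r_grid, rho = rho_grid)
  obs_counts <- obs_count_matrix(obs, times, max_size)
  surface$loglik <- purrr::pmap_dbl(surface, function(r, rho) {
    p <- sp_params(lambda = lambda, r = r, rho = rho, cycle = cycle,
                   Gamma = Gamma)
    sim <- sim_binned(p, times, max_size, n_sim, initial, crn_seed)
    fl <- 1 / (2 * n_sim)
    ll <- 0
    for (j in seq_along(times)) {
      pr <- pmax(sim$probs[, j], fl)
      pr <- pr / sum(pr)
      ll <- ll + sum(obs_counts[, j] * log(pr))
    }
    ll
  })
  best <- surface[which.max(surface$loglik), ]
  r_hat <- best$r; rho_hat <- best$rho
  on_edge <- r_hat %in% range(r_grid) || rho_hat %in% range(rho_grid)
  ci_r <- profile_ci(surface, "r")
  ci_rho <- profile_ci(surface, "rho")
  # predicted distribution at the MLE, for goodness of fit
  p_hat <- sp_params(lambda = lambda, r = r_hat, rho = rho_hat,
                     cycle = cycle, Gamma = Gamma)
  pred <- simulate_clone_ensemble("SP", p_hat, n_sim, times,
                                  max_size = max_size, initial = initial,
                                  seed = crn_seed)
  gof <- goodness_of_fit(obs, pred)
  structure(
    list(lambda = lambda, cycle = cycle,
         r = r_hat, rho = rho_hat,
         Gamma = if (is.null(Gamma))
           homeostatic_stratification_rate(rho_hat, lambda) else Gamma,
         ci_r = ci_r, ci_rho = ci_rho,
         surface = surface, r_grid = r_grid, rho_grid = rho_grid,
         loglik = best$loglik, on_grid_edge = on_edge,
         gof = gof, predicted = pred, observed = obs,
         n_sim = n_sim, initial = initial, seed = seed),
    class = "sp_fit")
}

obs_count_matrix <- function(obs, times, max_size) {
  m <- matrix(0, max_size, length(times))
  for (j in seq_along(times)) {
    o <- obs[obs$time == times[j], ]
    m[o$size, j] <- o$count
  }
  m
}

#' @export
print.sp_fit <- function(x, ...) {
  cat(sprintf(
    "<sp_fit> lambda %.3g /week (fixed); r = %.3g (95%% CI %.3g-%.3g); rho = %.3g (95%% CI %.3g-%.3g); Gamma = %.3g /week\n",
    x$lambda, x$r, x$ci_r[1], x$ci_r[2], x$rho, x$ci_rho[1], x$ci_rho[2],
    x$Gamma))
  cat(sprintf("  loglik %.2f over %d grid points; R2_T = %.3f, S_T = %.2f%s\n",
              x$loglik, nrow(x$surface), x$gof$R2_T, x$gof$S_T,
              if (x$on_grid_edge) "; MLE on grid edge" else ""))
  invisible(x)
}

#' Profile-likelihood confidence interval from a grid surface
#'
#' Profiles the log-likelihood surface over one parameter axis (maximizing
#' over the other) and returns the set where twice the log-likelihood drop
#' from the maximum stays within the chi-square(1) quantile, with endpoints
#' linearly interpolated between grid points.
#'
#' @param surface a tibble with columns `r`, `rho`, `loglik`
#' @param parameter `"r"` or `"rho"`
#' @param alpha significance level (default 0.05)
#' @return numeric interval `c(lower, upper)`, with attributes `flag`
#'   (`"ok"`, `"edge"`, `"flat"` or `"degenerate"`)
#' @export
profile_ci <- function(surface, parameter = c("r", "rho"), alpha = 0.05) {
  parameter <- match.arg(parameter)
  thr <- stats::qchisq(1 - alpha, df = 1) / 2
  prof <- surface |>
    dplyr::summarise(loglik = max(.data$loglik),
                     .by = dplyr::all_of(parameter)) |>
    dplyr::arrange(.data[[parameter]])
  theta <- prof[[parameter]]
  ll <- prof$loglik
  if (length(theta) == 1) {
    out <- c(theta, theta)
    attr(out, "flag") <- "degenerate"
    return(out)
  }
  if (diff(range(ll)) < 1e-12) {
    out <- range(theta)
    attr(out, "flag") <- "flat"
    return(out)
  }
  drop <- max(ll) - ll
  inside <- which(drop <= thr)
  lo_i <- min(inside); hi_i <- max(inside)
  interp <- function(i_in, i_out) {
    # crossing of drop == thr between grid points, linear in loglik
    frac <- (thr - drop[i_in]) / (drop[i_out] - drop[i_in])
    theta[i_in] + frac * (theta[i_out] - theta[i_in])
  }
  lo <- if (lo_i == 1) theta[1] else interp(lo_i, lo_i - 1)
  hi <- if (hi_i == length(theta)) theta[hi_i] else interp(hi_i, hi_i + 1)
  out <- c(lo, hi)
  attr(out, "flag") <- if (lo_i == 1 || hi_i == length(theta)) "edge" else "ok"
  out
}

#' Goodness of fit between observed and predicted clone-size frequencies
#'
#' For each time point, frequencies (in percent) are compared bin by bin:
#' `R2 = 1 - RSS/TSS` and `S = sqrt(RSS / n_bins)` (root-mean-square
#' residual in percentage points). `R2_T` and `S_T` are unweighted means
#' over time points.
#'
#' @param obs an `observed_clone_distribution`
#' @param pred a distribution with matching `time`, `size` and `prob`
#' @return a list with `per_time` (tibble of R2 and S by time), `R2_T`,
#'   `S_T`
#' @export
goodness_of_fit <- function(obs, pred) {
  joined <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(obs), "time", "size", obs_prob = "prob"),
    dplyr::select(tibble::as_tibble(pred), "time", "size", pred_prob = "prob"),
    by = c("time", "size"))
  if (nrow(joined) == 0)
    abort_invalid("observed and predicted distributions do not align.")
  per_time <- joined |>
    dplyr::reframe({
      o <- .data$obs_prob * 100
      p <- .data$pred_prob * 100
      rss <- sum((o - p)^2)
      tss <- sum((o - mean(o))^2)
      tibble::tibble(
        R2 = if (tss > 0) 1 - rss / tss else NA_real_,
        S = sqrt(rss / length(o)))
    }, .by = "time")
  list(per_time = per_time,
       R2_T = mean(per_time$R2),
       S_T = mean(per_time$S))
}

#' Coverage of observed clone-size proportions by model predictions
#'
#' For every (time, size bin), the observed proportion carries a standard
#' error of a proportion `sqrt(p(1-p)/n)`; a prediction is covered when it
#' falls inside the 95% interval `p +/- 1.96 SE`.
#'
#' @param obs an `observed_clone_distribution`
#' @param pred a distribution with matching `time`, `size` and `prob`
#' @return a list with `n_covered`, `n_total` and the per-bin `detail`
#' @export
ci_coverage <- function(obs, pred) {
  if (any(obs$n_clones == 0)) abort_invalid("time points with zero clones.")
  detail <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(obs), "time", "size", obs_prob = "prob",
                  "n_clones"),
    dplyr::select(tibble::as_tibble(pred), "time", "size",
                  pred_prob = "prob"),
    by = c("time", "size")) |>
    dplyr::mutate(
      se = sqrt(.data$obs_prob * (1 - .data$obs_prob) / .data$n_clones),
      covered = abs(.data$pred_prob - .data$obs_prob) <= 1.96 * .data$se)
  list(n_covered = sum(detail$covered), n_total = nrow(detail),
       detail = detail)
}
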