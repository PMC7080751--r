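#' Summarize the labeled clone population over time
#'
#' Computes the descriptive time course of a lineage-tracing experiment:
#' the mean basal size of surviving clones, the density of labeled clones
#' relative to the first time point, and the relative labeled basal-cell
#' fraction. Statistics are computed per animal and then averaged (mean
#' +/- SEM across animals), matching how such experiments are reported;
#' per-animal clone counts are used as the density proxy under a sampling
#' design with equal scored area per animal.
#'
#' @param clone_table a tibble with `mouse_id`, `time_days`, `n_basal`
#'   (extinct clones may be present as `n_basal == 0` and enter the
#'   density/labeled-fraction bookkeeping but not the surviving mean)
#' @return a `clone_timecourse` tibble: per time, `mean_size` (+/- SEM),
#'   `rel_density`, `rel_labeled_fraction`, and animal counts
#' @export
summarize_clone_timecourse <- function(clone_table) {
  stopifnot(all(c("mouse_id", "time_days", "n_basal") %in%
                  names(clone_table)))
  per_animal <- clone_table |>
    dplyr::summarise(
      n_clones = dplyr::n(),
      n_surviving = sum(.data$n_basal >= 1),
      mean_size = mean(.data$n_basal[.data$n_basal >= 1]),
      labeled_basal = sum(.data$n_basal),
      .by = c("mouse_id", "time_days"))
  out <- per_animal |>
    dplyr::summarise(
      n_mice = dplyr::n(),
      mean_size_sem = sd(.data$mean_size) / sqrt(dplyr::n()),
      mean_size = mean(.data$mean_size, na.rm = TRUE),
      density = mean(.data$n_surviving),
      density_sem = sd(.data$n_surviving) / sqrt(dplyr::n()),
      labeled = mean(.data$labeled_basal),
      labeled_sem = sd(.data$labeled_basal) / sqrt(dplyr::n()),
      .by = "time_days") |>
    dplyr::arrange(.data$time_days)
  first <- out[1, ]
  out <- out |>
    dplyr::mutate(
      rel_density = .data$density / first$density,
      rel_density_sem = .data$density_sem / first$density,
      rel_labeled_fraction = .data$labeled / first$labeled,
      rel_labeled_fraction_sem = .data$labeled_sem / first$labeled,
      missing = !is.finite(.data$mean_size))
  if (any(out$missing))
    rlang::warn("time point(s) with no surviving clones flagged as missing.")
  class(out) <- c("clone_timecourse", class(out))
  out
}

#' Scaling collapse of clone-size distributions
#'
#' At long times, neutral clonal competition drives the clone-size
#' distribution to a self-similar form: the probability of a clone
#' exceeding `x` times the mean size becomes time-invariant and
#' approaches `exp(-x)`. This function computes the empirical tails
#' `P(size >= x * mean)` on a common x-grid for each time point, their
#' maximum absolute deviation from `exp(-x)`, and the pairwise sup
#' distance between time points.
#'
#' @param clone_table a tibble with `time_days` and `n_basal` (>= 2 time
#'   points with surviving clones; times with a single clone are dropped)
#' @param x_grid grid of `size / mean size` values (default 40 points on
#'   `[0, 4]`; tails are counted, not smoothed)
#' @return a `scaling_curve` tibble with columns `time`, `x`, `tail`,
#'   `reference` (`exp(-x)`); attributes `deviation` (max |tail - e^-x|
#'   per time) and `pairwise` (sup distance between time curves)
#' @export
scaling_collapse <- function(clone_table, x_grid = seq(0, 4,
                                                       length.out = 40)) {
  stopifnot(all(c("time_days", "n_basal") %in% names(clone_table)))
  surv <- dplyr::filter(clone_table, .data$n_basal >= 1)
  keep <- surv |>
    dplyr::count(.data$time_days) |>
    dplyr::filter(.data$n > 1)
  surv <- dplyr::filter(surv, .data$time_days %in% keep$time_days)
  if (dplyr::n_distinct(surv$time_days) < 2)
    abort_invalid("scaling collapse needs >= 2 time points with > 1 clone.")
  curves <- surv |>
    dplyr::reframe({
      nb <- .data$n_basal
      m <- mean(nb)
      tibble::tibble(x = x_grid,
                     tail = vapply(x_grid, function(xx)
                       mean(nb >= xx * m), double(1)))
    }, .by = "time_days") |>
    dplyr::rename(time = "time_days") |>
    dplyr::mutate(reference = exp(-.data$x))
  stopifnot(all(curves$tail[curves$x == 0] == 1))
  dev <- curves |>
    dplyr::summarise(max_abs_dev = max(abs(.data$tail - .data$reference)),
                     .by = "time")
  wide <- tidyr::pivot_wider(curves, id_cols = "x", names_from = "time",
                             values_from = "tail")
  times <- setdiff(names(wide), "x")
  pw <- tidyr::expand_grid(t1 = times, t2 = times) |>
    dplyr::filter(.data$t1 < .data$t2) |>
    dplyr::mutate(sup_dist = purrr::map2_dbl(
      .data$t1, .data$t2, ~ max(abs(wide[[.x]] - wide[[.y]]))))
  structure(curves, deviation = dev, pairwise = pw,
            class = c("scaling_curve", class(curves)))
}

#' Sister-cell fate statistics of a division-outcome distribution
#'
#' Given the probabilities of the three daughter-pair outcomes of a
#' progenitor division — both daughters divide (`p_pp`), one divides and
#' one differentiates (`p_pd`), both differentiate (`p_dd`) — returns the
#' symmetric-division probability `r`, the per-daughter division
#' probability, and the correlation between sister fates. In the balanced
#' case (`p_pp == p_dd`, homeostasis) each daughter divides with
#' probability 1/2 and the sister-fate correlation is `4r - 1`: `r =
#' 0.25` is the uncorrelated null (independent fates), `r < 0.25` means
#' anti-correlated sisters. Unbalanced inputs additionally return the
#' fate skew `delta = (p_dd - p_pp) / (p_dd + p_pp)`.
#'
#' @param p_pp,p_pd,p_dd daughter-pair outcome probabilities (sum to 1)
#' @return a tibble with `r`, `p_divide`, `correlation` and (when
#'   unbalanced) `delta`
#' @export
sister_fate_statistics <- function(p_pp, p_pd, p_dd) {
  if (abs(p_pp + p_pd + p_dd - 1) > 1e-8 || any(c(p_pp, p_pd, p_dd) < 0))
    abort_invalid("outcome probabilities must be non-negative and sum to 1.")
  p_divide <- p_pp + p_pd / 2
  # correlation of the two Bernoulli "daughter divides" indicators
  cov <- p_pp - p_divide^2
  correlation <- if (p_divide %in% c(0, 1)) NA_real_ else
    cov / (p_divide * (1 - p_divide))
  balanced <- abs(p_pp - p_dd) < 1e-12
  out <- tibble::tibble(r = (p_pp + p_dd) / 2, p_divide = p_divide,
                        correlation = correlation)
  if (!balanced)
    out$delta <- (p_dd - p_pp) / (p_dd + p_pp)
  out
}

#' Compare two clone-size samples
#'
#' Two-sample Kolmogorov-Smirnov comparison of basal clone sizes, offered
#' for checking that clones labeled by different reporters share one
#' size distribution.
#'
#' @param sizes_a,sizes_b numeric vectors of basal clone sizes
#' @return a tibble with the KS statistic and p-value
#' @export
compare_clone_distributions <- function(sizes_a, sizes_b) {
  ks <- suppressWarnings(ks.test(sizes_a, sizes_b))
  tibble::tibble(statistic = unname(ks$statistic),
                 p_value = ks$p.value, method = "two-sample KS")
}
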