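#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a single-progenitor fit
#'
#' @param x an `sp_fit` from [mle_grid_search()]
#' @param ... unused
#' @return one row per parameter with estimate and 95% profile CI;
#'   `lambda` is the externally fixed rate, `Gamma` the homeostatic
#'   transform of `rho` (its CI is the transform of the `rho` CI)
#' @export
tidy.sp_fit <- function(x, ...) {
  g_ci <- homeostatic_stratification_rate(pmin(x$ci_rho, 1 - 1e-9), x$lambda)
  tibble::tibble(
    term = c("lambda", "r", "rho", "Gamma"),
    estimate = c(x$lambda, x$r, x$rho, x$Gamma),
    conf.low = c(NA, x$ci_r[1], x$ci_rho[1], g_ci[1]),
    conf.high = c(NA, x$ci_r[2], x$ci_rho[2], g_ci[2]),
    fixed = c(TRUE, FALSE, FALSE, FALSE))
}

#' @rdname tidy.sp_fit
#' @export
glance.sp_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    R2_T = x$gof$R2_T,
    S_T = x$gof$S_T,
    n_clones = sum(unique(x$observed[, c("time", "n_clones")])$n_clones),
    n_sim = x$n_sim,
    n_grid = nrow(x$surface),
    on_grid_edge = x$on_grid_edge)
}

#' Plot methods
#'
#' `autoplot.sp_fit()` draws the profile-likelihood surface over (r, rho)
#' with the MLE marked; `autoplot.clone_size_distribution()` and
#' `autoplot.observed_clone_distribution()` draw per-time clone-size
#' frequency panels; `autoplot.scaling_curve()` overlays the rescaled
#' tails on the `exp(-x)` reference; `autoplot.clone_timecourse()` shows
#' the mean clone size, relative density and labeled fraction over time.
#'
#' @param object the result object
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.sp_fit <- function(object, ...) {
  ggplot2::ggplot(object$surface,
                  ggplot2::aes(.data$r, .data$rho,
                               fill = .data$loglik - max(.data$loglik))) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = tibble::tibble(r = object$r, rho = object$rho),
                        ggplot2::aes(.data$r, .data$rho),
                        inherit.aes = FALSE, shape = 3, size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(-20, 0), oob = scales_squish) +
    ggplot2::labs(x = "symmetric division probability r",
                  y = "progenitor fraction rho",
                  fill = "Δ log-likelihood")
}

## minimal stand-in for scales::oob_squish (scales is installed with
## ggplot2, but keep the dependency surface explicit)
scales_squish <- function(x, range = c(-20, 0), ...) {
  pmin(pmax(x, range[1]), range[2])
}

#' @rdname autoplot.sp_fit
#' @export
autoplot.clone_size_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$size, .data$prob)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~time, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "basal cells per surviving clone", y = "frequency")
}

#' @rdname autoplot.sp_fit
#' @export
autoplot.observed_clone_distribution <- autoplot.clone_size_distribution

#' @rdname autoplot.sp_fit
#' @export
autoplot.scaling_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$tail,
                                       colour = factor(.data$time))) +
    ggplot2::geom_step() +
    ggplot2::geom_line(ggplot2::aes(y = .data$reference),
                       colour = "black", linetype = 2) +
    ggplot2::labs(x = "size / mean size", y = "P(size ≥ x · mean)",
                  colour = "time (days)")
}

#' @rdname autoplot.sp_fit
#' @export
autoplot.clone_timecourse <- function(object, ...) {
  long <- object |>
    dplyr::select("time_days", mean_size = "mean_size",
                  rel_density = "rel_density",
                  labeled_fraction = "rel_labeled_fraction") |>
    tidyr::pivot_longer(-"time_days")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_days, .data$value)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::labs(x = "days post induction", y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
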