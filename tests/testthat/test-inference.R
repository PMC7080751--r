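test_that("clone-size binning pools the tail and drops extinct clones", {
  tab <- tibble::tibble(mouse_id = "m", time_days = 10,
                        clone_id = as.character(1:5),
                        n_basal = c(1, 1, 2, 5, 0),
                        n_suprabasal = c(0, 0, 0, 0, 3))
  obs <- bin_clone_sizes(tab, max_size = 4)
  expect_equal(obs$count, c(2, 1, 0, 1))  # bins 1, 2, 3, 4+
  expect_equal(unique(obs$n_clones), 4)   # the basal-0 clone is excluded

  # pooling bound beyond the largest clone leaves an empty tail bin
  obs2 <- bin_clone_sizes(tab, max_size = 10)
  expect_equal(obs2$count[obs2$size == 10], 0)
  expect_error(bin_clone_sizes(tab[0, ]), class = "spclone_invalid_parameter")
})

test_that("multinomial log-likelihood is correct and floored", {
  obs <- tibble::tibble(time = 10, size = 1:2, count = c(6, 4),
                        prob = c(0.6, 0.4), n_clones = 10)
  class(obs) <- c("observed_clone_distribution", class(obs))
  sim <- tibble::tibble(time = 10, size = 1:2, count = c(50, 50),
                        prob = c(0.5, 0.5), n_surviving = 100,
                        n_simulated = 100, surviving_fraction = 1)
  expect_equal(clone_size_loglik(obs, sim), 10 * log(0.5))

  # matching proportions maximize the multinomial likelihood
  sim_match <- sim; sim_match$prob <- c(0.6, 0.4)
  ll_match <- clone_size_loglik(obs, sim_match)
  for (p1 in c(0.3, 0.5, 0.8)) {
    sim_alt <- sim; sim_alt$prob <- c(p1, 1 - p1)
    expect_gt(ll_match, clone_size_loglik(obs, sim_alt))
  }

  # observed mass in an unsimulated bin stays finite thanks to the floor
  sim_zero <- sim; sim_zero$prob <- c(1, 0)
  expect_warning(ll <- clone_size_loglik(obs, sim_zero), "zero simulated")
  expect_true(is.finite(ll))

  sim_bad <- sim; sim_bad$time <- 30
  expect_error(clone_size_loglik(obs, sim_bad),
               class = "spclone_invalid_parameter")
})

test_that("profile CI reproduces the quadratic-likelihood identity", {
  sigma <- 0.03
  r_axis <- seq(0.01, 0.5, by = 0.002)
  surface <- tidyr::expand_grid(r = r_axis, rho = 0.5)
  surface$loglik <- -(surface$r - 0.2)^2 / (2 * sigma^2)
  ci <- profile_ci(surface, "r")
  expect_equal(ci[1], 0.2 - 1.96 * sigma, tolerance = 1e-2)
  expect_equal(ci[2], 0.2 + 1.96 * sigma, tolerance = 1e-2)
  expect_equal(attr(ci, "flag"), "ok")

  # maximum on the grid edge gives a one-sided, flagged interval
  surface2 <- surface
  surface2$loglik <- -(surface2$r - 0.01)^2 / (2 * sigma^2)
  ci2 <- profile_ci(surface2, "r")
  expect_equal(attr(ci2, "flag"), "edge")
  expect_equal(ci2[1], 0.01)

  # degenerate single-point grid
  s3 <- tibble::tibble(r = 0.1, rho = 0.5, loglik = -1)
  ci3 <- profile_ci(s3, "r")
  expect_equal(attr(ci3, "flag"), "degenerate")
  expect_equal(unname(ci3), c(0.1, 0.1), ignore_attr = TRUE)

  # flat surface spans the whole grid
  s4 <- tidyr::expand_grid(r = c(0.1, 0.2, 0.3), rho = 0.5)
  s4$loglik <- -5
  ci4 <- profile_ci(s4, "r")
  expect_equal(attr(ci4, "flag"), "flat")
  expect_equal(unname(ci4), c(0.1, 0.3), ignore_attr = TRUE)
})

test_that("goodness-of-fit statistics follow their definitions", {
  obs <- tibble::tibble(time = 10, size = 1:2, count = c(60, 40),
                        prob = c(0.6, 0.4), n_clones = 100)
  pred_same <- obs
  g1 <- goodness_of_fit(obs, pred_same)
  expect_equal(g1$R2_T, 1)
  expect_equal(g1$S_T, 0)

  # two bins at 60/40% against a 50/50% prediction: RSS = 200 in
  # percent^2, S = sqrt(200/2) = 10, R2 = 1 - 200/200 = 0
  pred_flat <- obs; pred_flat$prob <- c(0.5, 0.5)
  g2 <- goodness_of_fit(obs, pred_flat)
  expect_equal(g2$per_time$S, 10)
  expect_equal(g2$per_time$R2, 0)

  # zero-variance observation: R2 undefined, reported as NA
  obs3 <- obs; obs3$prob <- c(0.5, 0.5)
  g3 <- goodness_of_fit(obs3, pred_flat)
  expect_true(is.na(g3$per_time$R2))
})

test_that("CI coverage counts and calibrates correctly", {
  obs <- tibble::tibble(time = 10, size = 1:4, count = c(120, 90, 60, 30),
                        prob = c(0.4, 0.3, 0.2, 0.1), n_clones = 300)
  class(obs) <- c("observed_clone_distribution", class(obs))
  pred <- obs
  cc <- ci_coverage(obs, pred)
  expect_equal(cc$n_covered, cc$n_total)

  pred_off <- obs
  pred_off$prob <- obs$prob + 10 * sqrt(obs$prob * (1 - obs$prob) / 300)
  expect_equal(ci_coverage(obs, pred_off)$n_covered, 0)

  # calibration: resampling observations from the prediction itself gives
  # about 95% coverage of the predicted proportions
  set.seed(77)
  p_true <- c(0.4, 0.3, 0.2, 0.1)
  hits <- replicate(500, {
    counts <- as.vector(rmultinom(1, 300, p_true))
    o <- tibble::tibble(time = 10, size = 1:4, count = counts,
                        prob = counts / 300, n_clones = 300)
    pr <- tibble::tibble(time = 10, size = 1:4, prob = p_true)
    cov <- ci_coverage(o, pr)
    cov$n_covered / cov$n_total
  })
  expect_gt(mean(hits), 0.92)
  expect_lt(mean(hits), 0.985)
})

test_that("grid search returns a coherent fit object", {
  p <- eso_params()
  ct <- generate_lineage_experiment(
    p, lineage_design(times = c(30, 84), animals = c(3, 3),
                      target_clones = c(300, 300)), seed = 81)
  obs <- bin_clone_sizes(ct, max_size = 15)
  expect_warning(
    fit <- mle_grid_search(obs, lambda = 2.9, cycle = p$cycle,
                           r_grid = c(0.05, 0.1, 0.15, 0.6),
                           rho_grid = c(0.5, 0.65, 0.8),
                           n_sim = 4000, seed = 82),
    "skipped")
  # the MLE attains the surface maximum
  expect_equal(fit$loglik, max(fit$surface$loglik))
  # the homeostatic identity holds exactly at the estimate
  expect_equal(fit$Gamma,
               homeostatic_stratification_rate(fit$rho, fit$lambda))
  # profile CIs contain the MLE
  expect_true(fit$ci_r[1] <= fit$r && fit$r <= fit$ci_r[2])
  expect_true(fit$ci_rho[1] <= fit$rho && fit$rho <= fit$ci_rho[2])
  td <- tidy(fit)
  expect_setequal(td$term, c("lambda", "r", "rho", "Gamma"))
  gl <- glance(fit)
  expect_equal(gl$n_clones, sum(unique(obs[, c("time", "n_clones")])$n_clones))

  # truth outside the grid: the MLE lands on the boundary and is flagged
  fit_edge <- mle_grid_search(obs, lambda = 2.9, cycle = p$cycle,
                              r_grid = c(0.3, 0.4), rho_grid = c(0.3, 0.4),
                              n_sim = 2000, seed = 83)
  expect_true(fit_edge$on_grid_edge)
  expect_error(mle_grid_search(obs, 2.9, p$cycle, r_grid = numeric(0),
                               rho_grid = 0.5),
               class = "spclone_invalid_parameter")
})
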