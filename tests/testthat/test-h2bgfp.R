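test_that("normalization fixes the time-0 keratinocyte mean at 1 and is idempotent", {
  tab <- toy_intensity_table()
  norm <- normalize_intensities(tab)
  expect_equal(mean(norm$intensity[norm$time_days == 0 & !norm$is_leukocyte]),
               1)
  twice <- normalize_intensities(norm)
  expect_equal(twice$intensity, norm$intensity)

  # leukocyte-only time 0 cannot serve as reference
  bad <- tab
  bad$is_leukocyte[bad$time_days == 0] <- TRUE
  expect_error(normalize_intensities(bad),
               class = "spclone_invalid_parameter")
})

test_that("leukocytes are flagged out of downstream statistics", {
  tab <- toy_intensity_table()
  # add extreme leukocytes everywhere; keratinocyte statistics must not move
  leu <- tab
  leu$cell_id <- paste0("leu_", leu$cell_id)
  leu$intensity <- 1000
  leu$is_leukocyte <- TRUE
  both <- normalize_intensities(dplyr::bind_rows(tab, leu))
  only <- normalize_intensities(tab)
  expect_equal(
    mean(both$intensity[!both$is_leukocyte & both$time_days == 7]),
    mean(only$intensity[only$time_days == 7]))
  est_a <- estimate_division_rate(both, n_bootstrap = 100, seed = 1)
  est_b <- estimate_division_rate(only, n_bootstrap = 100, seed = 1)
  expect_equal(est_a$rate, est_b$rate)
})

test_that("log2 slope is exact on noiseless halving data", {
  tab <- tidyr::expand_grid(mouse_id = "m1", time_days = c(0, 7, 14),
                            fov_id = c("f1", "f2", "f3"),
                            cell_id = as.character(1:20)) |>
    dplyr::mutate(intensity = 2^(-time_days / 7), is_leukocyte = FALSE)
  est <- estimate_division_rate(tab, n_bootstrap = 100, seed = 1)
  expect_equal(est$rate, 1, tolerance = 1e-9)
  expect_error(
    estimate_division_rate(dplyr::filter(tab, time_days == 0)),
    class = "spclone_invalid_parameter")
})

test_that("simulation_fit agrees with log2_slope on simulated chases", {
  p <- eso_params()
  tab <- normalize_intensities(
    generate_h2bgfp_experiment(p, small_chase(), seed = 41))
  slope <- estimate_division_rate(tab, n_bootstrap = 100, seed = 42)
  simfit <- estimate_division_rate(tab, method = "simulation_fit",
                                   template = p,
                                   lambda_grid = seq(1.9, 3.9, by = 0.25),
                                   n_sim = 3000, seed = 43)
  expect_lt(abs(slope$rate - 2.9) / 2.9, 0.1)
  expect_lt(abs(simfit$rate - 2.9) / 2.9, 0.15)
  expect_true(simfit$ci95[1] <= simfit$rate && simfit$rate <= simfit$ci95[2])
})

test_that("cycle-shape fitting recovers the generating shape", {
  p <- eso_params(shape = 8)
  tab <- normalize_intensities(
    generate_h2bgfp_experiment(p, small_chase(field_cv = 0, noise_cv = 0.1),
                               seed = 51))
  fit <- fit_cycle_shape(tab, lambda = 2.9, r = p$r, rho = p$rho,
                         shape_grid = c(1, 2, 4, 8, 16, 32),
                         t_min_grid = 0.5, n_sim = 3000, seed = 52)
  grid_shapes <- c(1, 2, 4, 8, 16, 32)
  best_pos <- match(fit$best$shape, grid_shapes)
  expect_lte(abs(best_pos - match(8, grid_shapes)), 1)
  # the conservative solution is never narrower than the best fit
  expect_lte(fit$conservative$shape, fit$best$shape)
  expect_error(fit_cycle_shape(tab, 2.9, shape_grid = numeric(0)),
               class = "spclone_invalid_parameter")
})

test_that("clock-like data reject the exponential cycle law", {
  T_cc <- 7 / 2.9
  pdet <- sp_params(lambda = 2.9, r = 0.1, rho = 0.65,
                    cycle = cycle_distribution("deterministic", T_cc))
  tab <- normalize_intensities(
    generate_h2bgfp_experiment(pdet, small_chase(field_cv = 0,
                                                 noise_cv = 0.1),
                               seed = 61))
  fit <- fit_cycle_shape(tab, lambda = 2.9, r = 0.1, rho = 0.65,
                         shape_grid = c(1, 4, 16, 64), t_min_grid = 0,
                         n_sim = 3000, seed = 62)
  prof <- fit$profile
  d1 <- prof$distance[prof$shape == 1]
  expect_gt(d1 - min(prof$distance), 3.84 / 2)
  expect_gt(fit$best$shape, 1)
})

test_that("label-retaining cells are counted per cell class", {
  # spike-in: 4 non-diluting keratinocytes among 1923 at 18 days
  t0 <- tibble::tibble(mouse_id = "m1", time_days = 0, fov_id = "f1",
                       cell_id = sprintf("a%d", 1:500), intensity = 1,
                       is_leukocyte = FALSE)
  t18_ker <- tibble::tibble(mouse_id = "m2", time_days = 18, fov_id = "f2",
                            cell_id = sprintf("b%d", 1:1923),
                            intensity = c(rep(1, 4), rep(0.01, 1919)),
                            is_leukocyte = FALSE)
  t18_leu <- tibble::tibble(mouse_id = "m2", time_days = 18, fov_id = "f2",
                            cell_id = sprintf("l%d", 1:40), intensity = 1,
                            is_leukocyte = TRUE)
  tab <- dplyr::bind_rows(t0, t18_ker, t18_leu)
  res <- detect_lrcs(tab, at_time = 18)
  expect_equal(res$lrc_fraction[res$class == "keratinocyte"], 4 / 1923)
  expect_equal(res$lrc_fraction[res$class == "leukocyte"], 1)
  expect_error(detect_lrcs(tab, at_time = 12),
               class = "spclone_invalid_parameter")

  # a simulated esophageal chase has essentially no keratinocyte LRCs
  p <- eso_params()
  sim <- normalize_intensities(
    generate_h2bgfp_experiment(p, small_chase(), seed = 71))
  res_sim <- detect_lrcs(sim, at_time = 18)
  expect_lt(res_sim$lrc_fraction[res_sim$class == "keratinocyte"], 0.005)
})
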