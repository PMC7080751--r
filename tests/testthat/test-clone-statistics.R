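test_that("homeostatic flux balance reproduces every tabulated stratification rate", {
  # (rho %, lambda /week) -> Gamma /week at one decimal, five tissues
  rows <- list(c(0.65, 2.9, 5.4), c(0.56, 2.9, 3.7), c(0.53, 2.0, 2.3),
               c(0.54, 1.5, 1.8), c(0.61, 1.2, 1.9))
  for (row in rows)
    expect_equal(round(homeostatic_stratification_rate(row[1], row[2]), 1),
                 row[3])
  expect_equal(homeostatic_stratification_rate(0.5, 1.7), 1.7)
  expect_error(homeostatic_stratification_rate(1.2, 2),
               class = "spclone_invalid_parameter")
})

test_that("sister-fate statistics match exhaustive enumeration", {
  # uncorrelated daughters dividing with probability 1/2: r = 0.25
  s <- sister_fate_statistics(0.25, 0.5, 0.25)
  expect_equal(s$r, 0.25)
  expect_equal(s$correlation, 0)

  # enumeration oracle: correlation of the two "daughter divides"
  # indicators computed from the joint outcome table
  enum_corr <- function(p_pp, p_pd, p_dd) {
    # joint outcomes (a, b) with probabilities; PD splits evenly by symmetry
    probs <- c(p_pp, p_pd / 2, p_pd / 2, p_dd)
    a <- c(1, 1, 0, 0); b <- c(1, 0, 1, 0)
    ea <- sum(probs * a); eb <- sum(probs * b)
    (sum(probs * a * b) - ea * eb) / sqrt(ea * (1 - ea) * eb * (1 - eb))
  }
  for (r in c(0.05, 0.1, 0.2, 0.25, 0.4)) {
    s <- sister_fate_statistics(r, 1 - 2 * r, r)
    expect_equal(s$correlation, enum_corr(r, 1 - 2 * r, r))
    expect_equal(s$correlation, 4 * r - 1)
    expect_equal(s$p_divide, 0.5)  # balance for every r
  }
  expect_equal(sister_fate_statistics(0.10, 0.80, 0.10)$correlation, -0.6)

  # purely asymmetric divisions: perfectly anti-correlated sisters
  s0 <- sister_fate_statistics(0, 1, 0)
  expect_equal(s0$r, 0)
  expect_equal(s0$correlation, -1)

  # unbalanced fates report the differentiation skew delta
  su <- sister_fate_statistics(0.1, 0.6, 0.3)
  expect_equal(su$delta, (0.3 - 0.1) / (0.3 + 0.1))
  expect_error(sister_fate_statistics(0.5, 0.4, 0.3),
               class = "spclone_invalid_parameter")
})

test_that("clone time course reports sizes, density and labeled fraction", {
  # all clones single cells at t = 0
  tab0 <- tibble::tibble(mouse_id = rep(c("m1", "m2"), each = 5),
                         time_days = 0, clone_id = as.character(1:10),
                         n_basal = 1, n_suprabasal = 0)
  tc0 <- summarize_clone_timecourse(tab0)
  expect_equal(tc0$mean_size, 1)
  expect_equal(tc0$rel_density, 1)

  # neutral-drift coarsening: surviving clones grow while density falls
  p <- eso_params()
  cl <- simulate_clones(p, 5000, c(10, 30, 84, 180), seed = 91) |>
    dplyr::mutate(mouse_id = sprintf("m%d", (clone_id - 1) %% 3 + 1),
                  time_days = time)
  tc <- summarize_clone_timecourse(cl)
  expect_true(all(diff(tc$mean_size) > 0))
  expect_true(all(diff(tc$rel_density) < 0))

  # homeostasis: the labeled basal fraction shows no time trend when
  # labeling starts from representative basal cells
  cl_rep <- purrr::map_dfr(1:3, function(m)
    simulate_clones(p, 4000, c(10, 30, 84, 180),
                    initial = "basal_representative", seed = 95 + m) |>
      dplyr::mutate(mouse_id = sprintf("m%d", m), time_days = time))
  tc_rep <- summarize_clone_timecourse(cl_rep)
  trend <- suppressWarnings(
    cor.test(tc_rep$time_days, tc_rep$rel_labeled_fraction,
             method = "kendall"))
  expect_gt(trend$p.value, 0.05)
})

test_that("late-time clone sizes collapse onto the exponential scaling form", {
  p <- eso_params()
  cl <- simulate_clones(p, 30000, c(10, 84, 180), seed = 97) |>
    dplyr::mutate(time_days = time)
  sc <- scaling_collapse(cl)
  # the rescaled tail near x = 1 approaches exp(-1)
  late <- sc[sc$time == 180, ]
  i <- which.min(abs(late$x - 1))
  n_surv <- sum(cl$n_basal[cl$time == 180] >= 1)
  mc_se <- sqrt(late$tail[i] * (1 - late$tail[i]) / n_surv)
  expect_lt(abs(late$tail[i] - exp(-late$x[i])), 3 * mc_se + 0.02)
  # tails are monotone with tail(0) = 1 (asserted inside, spot-check here)
  expect_true(all(sc$tail[sc$x == 0] == 1))
  for (tt in unique(sc$time))
    expect_true(all(diff(sc$tail[sc$time == tt]) <= 0))
  # the two late time points collapse onto each other; the comparison of
  # the rescaled staircase tails carries a lattice granularity of about
  # half a size step (1/mean) per curve
  pw <- attr(sc, "pairwise")
  m84 <- mean(cl$n_basal[cl$time == 84 & cl$n_basal >= 1])
  m180 <- mean(cl$n_basal[cl$time == 180 & cl$n_basal >= 1])
  lattice <- 0.5 * (1 / m84 + 1 / m180)
  expect_lt(pw$sup_dist[pw$t1 == "180" & pw$t2 == "84"], lattice + 0.03)
  # ... while the early time point deviates from the scaling form
  dev <- attr(sc, "deviation")
  expect_gt(dev$max_abs_dev[dev$time == 10],
            2 * dev$max_abs_dev[dev$time == 180])
})
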