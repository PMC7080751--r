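test_that("degenerate parameter limits behave as the model dictates", {
  # r = 0: purely asymmetric divisions keep exactly one progenitor
  p0 <- sp_params(lambda = 2.9, r = 0, rho = 0.65)
  cl <- simulate_clones(p0, 200, c(5, 20, 60), seed = 1)
  expect_true(all(cl$n_progenitor == 1))

  # enormous stratification rate: differentiating cells leave instantly
  pfast <- sp_params(lambda = 2.9, r = 0.1, rho = 0.65, Gamma = 1000)
  clf <- simulate_clones(pfast, 500, c(10, 40), seed = 2)
  expect_lt(mean(clf$n_diff_basal), 0.01)

  # record-time validation
  expect_error(simulate_clone(p0, record_times = numeric(0)),
               class = "spclone_invalid_parameter")
  expect_error(sp_params(lambda = 2.9, r = 0.6, rho = 0.65),
               class = "spclone_invalid_parameter")
})

test_that("expected progenitor number is a martingale at criticality", {
  p <- sp_params(lambda = 2.9, r = 0.1, rho = 0.65)  # exponential cycles
  cl <- simulate_clones(p, 1e5, c(10, 30, 84), seed = 3)
  for (tt in c(10, 30, 84)) {
    x <- cl$n_progenitor[cl$time == tt]
    expect_lt(abs(mean(x) - 1), 3 * sd(x) / sqrt(length(x)))
  }
  # and for gamma cycles
  pg <- eso_params()
  clg <- simulate_clones(pg, 5e4, c(30, 84), seed = 4)
  for (tt in c(30, 84)) {
    x <- clg$n_progenitor[clg$time == tt]
    expect_lt(abs(mean(x) - 1), 3 * sd(x) / sqrt(length(x)))
  }
})

test_that("exponential-cycle engine matches the critical birth-death closed forms", {
  # with exponential cycles the progenitor count is a critical birth-death
  # process with birth = death = r * lambda: P(survive) = 1/(1 + r lambda t)
  # and E[progenitors | survive] = 1 + r lambda t
  lam <- 2.9; r <- 0.1
  p <- sp_params(lambda = lam, r = r, rho = 0.65)
  times <- c(30, 84, 180)
  cl <- simulate_clones(p, 5e4, times, seed = 5)
  for (tt in times) {
    x <- cl$n_progenitor[cl$time == tt]
    rlt <- r * (lam / 7) * tt
    surv <- x >= 1
    p_theory <- 1 / (1 + rlt)
    expect_lt(abs(mean(surv) - p_theory),
              3 * sqrt(p_theory * (1 - p_theory) / length(x)))
    xs <- x[surv]
    expect_lt(abs(mean(xs) - (1 + rlt)), 3 * sd(xs) / sqrt(length(xs)))
  }
})

test_that("mean basal size over all initiated clones approaches 1/rho", {
  p <- sp_params(lambda = 2.9, r = 0.1, rho = 0.65)
  cl <- simulate_clones(p, 5e4, 180, seed = 6)
  expect_lt(abs(mean(cl$n_basal) - 1 / 0.65),
            3 * sd(cl$n_basal) / sqrt(nrow(cl)))
})

test_that("the non-Markovian engine reproduces a direct Gillespie oracle", {
  lam_day <- 2.9 / 7; r <- 0.12; rho <- 0.6
  gam_day <- (rho * 2.9 / (1 - rho)) / 7
  set.seed(7)
  n <- 3000
  oracle <- vapply(seq_len(n), function(i)
    gillespie_sp_basal(lam_day, r, gam_day, 30), integer(1))
  p <- sp_params(lambda = 2.9, r = r, rho = rho)
  engine <- simulate_clones(p, n, 30, seed = 8)$n_basal
  tab <- rbind(tabulate(pmin(oracle, 10) + 1, 11),
               tabulate(pmin(engine, 10) + 1, 11))
  expect_gt(suppressWarnings(stats::chisq.test(tab))$p.value, 0.001)
})

test_that("ensembles start as single cells and condition on survival", {
  p <- eso_params()
  d <- simulate_clone_ensemble("SP", p, 2000, c(0, 30), max_size = 8,
                               seed = 9)
  d0 <- d[d$time == 0, ]
  expect_equal(d0$surviving_fraction[1], 1)
  expect_equal(d0$prob[d0$size == 1], 1)
  d30 <- d[d$time == 30, ]
  expect_lt(d30$surviving_fraction[1], 1)
  expect_equal(sum(d30$prob), 1)
  expect_error(simulate_clone_ensemble("TwoSC", p, 10, 5),
               class = "spclone_invalid_parameter")
})

test_that("label dilution follows division counts exactly", {
  # chase time 0, zero noise: the initial intensity law is returned as is
  p <- eso_params()
  d0 <- simulate_dilution(p, c(0, 7), 2000,
                          init_intensity = list(mean = 2, cv = 0.4),
                          seed = 10)
  at0 <- d0$intensity[d0$time_days == 0]
  expect_equal(length(at0), 2000)
  expect_lt(abs(mean(at0) - 2), 3 * sd(at0) / sqrt(2000))
  expect_lt(abs(sd(at0) / mean(at0) - 0.4), 0.03)

  # deterministic cycles, rho = 1, no noise: intensities sit on exactly
  # the two division levels floor(t/T) and floor(t/T) + 1
  T_cc <- 2; tt <- 5
  pdet <- sp_params(lambda = 7 / T_cc, r = 0.1, rho = 1,
                    cycle = cycle_distribution("deterministic", T_cc))
  dd <- simulate_dilution(pdet, c(0, tt), 1000,
                          init_intensity = list(mean = 1, cv = 0), seed = 11)
  v <- dd$intensity[dd$time_days == tt]
  lv <- sort(unique(round(-log2(v), 9)))
  expect_setequal(lv, c(floor(tt / T_cc), floor(tt / T_cc) + 1))

  # exponential cycles, rho = 1: divisions are Poisson, so mean log2
  # intensity drops by lambda * t
  pex <- sp_params(lambda = 2.9, r = 0.1, rho = 1)
  de <- simulate_dilution(pex, c(0, 12), 3000,
                          init_intensity = list(mean = 1, cv = 0), seed = 12)
  l2 <- log2(de$intensity[de$time_days == 12])
  drop <- -mean(l2)
  expect_lt(abs(drop - (2.9 / 7) * 12), 3 * sd(l2) / sqrt(length(l2)))

  expect_error(simulate_dilution(p, c(0, 7), 100, measurement_noise_cv = -1),
               class = "spclone_invalid_parameter")
  expect_error(simulate_dilution(p, c(7, 12), 100),
               class = "spclone_invalid_parameter")
})

test_that("labeled basal-cell mass stays flat under homeostatic initiation", {
  p <- eso_params()
  times <- c(10, 30, 60, 84, 120, 180)
  means <- vapply(1:3, function(m) {
    cl <- simulate_clones(p, 4000, times, initial = "basal_representative",
                          seed = 100 + m)
    vapply(times, function(tt) mean(cl$n_basal[cl$time == tt]), double(1))
  }, double(length(times)))
  ens <- rowMeans(means)
  trend <- suppressWarnings(cor.test(times, ens, method = "kendall"))
  expect_gt(trend$p.value, 0.05)
  # mean labeled mass per initiated cell stays near 1
  expect_lt(max(abs(ens - 1)), 0.15)
})
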