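test_that("AR(1) covariates have the requested autocorrelation", {
  cfg0 <- scenario_config(n_years = 2000, sst_ar = 0, pred_missing = 0,
                          mass_missing = 0)
  cv0 <- generate_covariates(cfg0, seed = 1)
  r0 <- acf(cv0$matrix$S0, plot = FALSE)$acf[2]
  expect_lt(abs(r0), 3 / sqrt(2000))

  cfg7 <- scenario_config(n_years = 2000, sst_ar = 0.7, pred_missing = 0,
                          mass_missing = 0)
  cv7 <- generate_covariates(cfg7, seed = 2)
  r7 <- acf(cv7$matrix$S0, plot = FALSE)$acf[2]
  expect_lt(abs(r7 - 0.7), 0.05)
})

test_that("generation is bit-identical for a fixed seed", {
  cfg <- scenario_study_like()
  s1 <- simulate_scenario(cfg, seed = 77)
  s2 <- simulate_scenario(cfg, seed = 77)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$survival, s2$survival)
  expect_identical(as.data.frame(s1$covariates), as.data.frame(s2$covariates))
})

test_that("covariate-free growth matches the dominant eigenvalue", {
  cfg <- scenario_config(
    n_years = 28, initial_females = 2200,
    surv_coef = survival_coefficients(logit(0.4), logit(0.9),
                                      indicators = c(0, 0, 0)),
    prod_coef = productivity_coefficients(logit(0.5),
                                          indicators = rep(0, 10)),
    pred_missing = 0, mass_missing = 0)
  cov <- generate_covariates(cfg, seed = 3)
  lam_true <- growth_rate(vital_rates(0.4, 0.9, 0.5))
  g <- replicate(200, {
    tr <- generate_truth(cfg, cov, seed = sample.int(1e6, 1))
    (tr$N[6, 28] / tr$N[6, 1])^(1 / 27)
  })
  se <- sd(g) / sqrt(length(g))
  expect_lt(abs(mean(g) - lam_true), 3 * se + 0.003)
})

test_that("negative density dependence damps trajectory variance", {
  # stationary baseline (growth factor ~ 1), centring pinned at the
  # equilibrium abundance and a long horizon, so damping of the
  # demographic random walk dominates the delayed-feedback oscillation
  mk <- function(bC, ind) scenario_config(
    n_years = 150, initial_females = 500,
    prod_coef = productivity_coefficients(
      logit(0.58), beta = c(rep(0, 9), bC),
      indicators = c(rep(0, 9), ind)),
    surv_coef = survival_coefficients(logit(0.50), logit(0.915),
                                      indicators = c(0, 0, 0)),
    pred_missing = 0, mass_missing = 0, survival_window = 8,
    c_center = 500, c_scale = 150)
  cfg_dd <- mk(-1, 1)
  cfg_di <- mk(0, 0)
  v_dd <- v_di <- numeric(15)
  for (r in 1:15) {
    cov <- generate_covariates(cfg_dd, seed = 400 + r)
    tr_dd <- generate_truth(cfg_dd, cov, seed = 900 + r, refine_c = FALSE)
    tr_di <- generate_truth(cfg_di, cov, seed = 900 + r, refine_c = FALSE)
    v_dd[r] <- var(log(pmax(tr_dd$N[6, ], 1)))
    v_di[r] <- var(log(pmax(tr_di$N[6, ], 1)))
  }
  expect_lt(median(v_dd), median(v_di))
})

test_that("a zero initial population stays at zero", {
  cfg <- scenario_config(initial_females = 0, pred_missing = 0,
                         mass_missing = 0)
  cov <- generate_covariates(cfg, seed = 6)
  tr <- generate_truth(cfg, cov, seed = 7)
  expect_true(all(tr$N == 0))
  expect_true(all(tr$chicks == 0))
})

test_that("observations are unbiased around the latent values", {
  sim <- fixture_sim()
  cfg <- sim$config

  # zero observation variance reproduces the latent values exactly
  cfg0 <- cfg; cfg0$s2 <- 0
  obs0 <- generate_observations(sim$truth, cfg0, seed = 8)
  expect_equal(obs0$counts$pairs, as.numeric(sim$truth$N[6, ]))
  expect_equal(obs0$counts$chicks, 2 * sim$truth$chicks)

  # Monte Carlo: the mean of replicate observation sets matches the truth
  reps <- sapply(1:1000, function(r)
    suppressMessages(generate_observations(sim$truth, cfg, seed = r))$counts$pairs)
  se <- apply(reps, 1, sd) / sqrt(ncol(reps))
  expect_true(all(abs(rowMeans(reps) - sim$truth$N[6, ]) <= 3 * se + 0.5))

  # an empty survival window yields an empty survival table
  cfgn <- cfg; cfgn$survival_window <- 0
  obsn <- generate_observations(sim$truth, cfgn, seed = 9)
  expect_equal(nrow(obsn$survival), 0)
})

test_that("the packaged fixture has the study-like shape", {
  sim <- fixture_sim()
  expect_identical(sim$counts, study_like_fixture()$counts)

  # declines in the first segment, near-flat after the break
  bs <- fit_broken_stick(sim$counts$year, sim$counts$pairs)
  expect_lt(bs$rates_pct[1], -4)
  expect_gt(bs$rates_pct[2], bs$rates_pct[1] + 3)
  expect_gt(bs$rates_pct[2], -3)

  # missingness mirrors the emulated data availability: predation observed
  # only from the 17th season (2001 analogue), mass from the 5th (1989)
  mk <- attr(sim$covariates, "mask")
  expect_identical(unname(mk[, "P"]), sim$counts$year >= 2001)
  expect_identical(unname(mk[, "A"]), sim$counts$year >= 1989)
  # survival window: final 8 seasons, both age classes
  expect_setequal(unique(sim$survival$year), 2005:2012)
  expect_equal(nrow(sim$survival), 16)
})
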