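test_that("the fitted-model object provides the standard methods", {
  fit <- small_fit()
  expect_s3_class(fit, "sspm")
  expect_output(print(fit), "state-space population model")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.sspm")
  expect_output(print(sm), "Inclusion probabilities")

  cf <- coef(fit)
  expect_true(all(c("alpha_f0", "alpha_a0", "beta_0", "beta_10") %in%
                    names(cf)))
  expect_true(all(is.finite(cf)))

  ft <- fitted(fit)
  expect_equal(length(ft), nrow(fit$data$counts))
  rs <- residuals(fit)
  expect_equal(unname(rs), fit$data$counts$pairs - unname(ft))

  pr <- predict(fit, type = "rates")
  expect_named(pr, c("phi_f", "phi_a", "b"))
  expect_true(all(pr$phi_a$mean > 0 & pr$phi_a$mean < 1))

  sims <- simulate(fit, nsim = 25, seed = 2)
  expect_equal(dim(sims), c(25, nrow(fit$data$counts)))
  expect_true(all(sims >= 0))

  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})

test_that("fitting validates its inputs", {
  sim <- small_sim()
  expect_error(sspm(sim$counts[, 1:2], sim$covariates,
                    control = micro_control(1)), "columns")
  expect_error(sspm(sim$counts, sim$covariates,
                    control = micro_control(1)), "replicates.*s2|s2")
  bad_sv <- data.frame(year = sim$counts$year[1], age_class = "adultish",
                       estimate = 0.8, ci_low = 0.7, ci_high = 0.9)
  expect_error(sspm(sim$counts, sim$covariates, survival = bad_sv,
                    s2 = 100, control = micro_control(1)),
               "fledgling")
  cov2 <- sim$covariates
  cov2$year <- cov2$year + 1             # year grids no longer match
  expect_error(sspm(sim$counts, cov2, s2 = 100,
                    control = micro_control(1)), "match")
})

test_that("a counts-only fit (no survival window) runs", {
  sim <- small_sim()
  fit <- cached("counts_only_fit",
    sspm(sim$counts, sim$covariates, survival = NULL,
         replicates = sim$replicates, control = micro_control(19)))
  expect_s3_class(fit, "sspm")
  expect_true(all(is.finite(monitored_rhat(fit))))
  expect_false("sigma_rw" %in% rownames(fit$coefficients) &&
                 !fit$data$predation_missing)
})

test_that("marginalized and full-stage samplers agree", {
  sim <- small_sim()
  fit_m <- small_fit()   # marginal representation
  fit_f <- cached("full_variant_fit",
    sspm(sim$counts, sim$covariates, survival = sim$survival,
         replicates = sim$replicates, control = micro_control(23),
         latent = "full"))
  # posterior means of the annual rates and key coefficients agree within
  # Monte-Carlo noise of the micro budget
  expect_lt(max(abs(fit_m$rates$phi_a$mean - fit_f$rates$phi_a$mean)), 0.05)
  expect_lt(max(abs(fit_m$rates$b$mean - fit_f$rates$b$mean)), 0.05)
  expect_lt(abs(coef(fit_m)[["alpha_a0"]] - coef(fit_f)[["alpha_a0"]]), 0.4)
  expect_lt(max(abs(fit_m$states$breeders$mean - fit_f$states$breeders$mean) /
                  pmax(fit_m$states$breeders$mean, 1)), 0.15)
})

test_that("doubling the series length does not widen survival intervals", {
  mk <- function(n) {
    cfg <- scenario_config(n_years = n, initial_females = 1000,
                           pred_missing = 0, mass_missing = 0,
                           pred_drift_early = 0,
                           survival_window = round(n / 3))
    sim <- simulate_scenario(cfg, seed = 71)
    sspm(sim$counts, sim$covariates, survival = sim$survival,
         replicates = sim$replicates,
         control = mcmc_control(seed = 3, chains = 2, iterations = 6000,
                                thin = 10, burn_in = 100, adapt = 500))
  }
  w <- sapply(list(cached("contract_16", mk(16)),
                   cached("contract_32", mk(32))), function(f)
    median(f$rates$phi_a$q97.5 - f$rates$phi_a$q2.5))
  expect_lt(w[2], w[1] * 1.05)
})
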