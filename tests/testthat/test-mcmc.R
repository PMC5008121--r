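test_that("a seed is mandatory and runs are reproducible", {
  expect_error(mcmc_control(), "seed")

  sim <- small_sim()
  f1 <- sspm(sim$counts, sim$covariates, survival = sim$survival,
             replicates = sim$replicates, control = micro_control(31))
  f2 <- sspm(sim$counts, sim$covariates, survival = sim$survival,
             replicates = sim$replicates, control = micro_control(31))
  m1 <- do.call(rbind, lapply(f1$draws$samples, as.matrix))
  m2 <- do.call(rbind, lapply(f2$draws$samples, as.matrix))
  expect_identical(m1, m2)
})

test_that("conjugate sub-model posterior matches the Beta closed form", {
  cc <- conjugate_check()
  mcse <- sd(cc$draws) / sqrt(coda::effectiveSize(coda::mcmc(cc$draws)))
  expect_lt(abs(mean(cc$draws) - cc$beta_mean), 4 * mcse + 1e-4)
  expect_lt(abs(sd(cc$draws) / cc$beta_sd - 1), 0.2)
})

test_that("Rhat is exactly 1 on duplicated chains and separates bad ones", {
  rh <- gelman_rubin(duplicated_chains())
  expect_equal(unname(rh), c(1, 1), tolerance = 1e-12)

  # chains from different distributions are flagged
  set.seed(13)
  bad <- coda::mcmc.list(
    coda::mcmc(matrix(rnorm(300, 0), ncol = 1,
                      dimnames = list(NULL, "x"))),
    coda::mcmc(matrix(rnorm(300, 10), ncol = 1,
                      dimnames = list(NULL, "x"))))
  expect_gt(gelman_rubin(bad)[["x"]], 3)

  # long i.i.d. chains from one distribution approach 1
  set.seed(14)
  good <- coda::mcmc.list(lapply(1:3, function(i)
    coda::mcmc(matrix(rnorm(5000), ncol = 1,
                      dimnames = list(NULL, "x")))))
  expect_lt(gelman_rubin(good)[["x"]], 1.01)

  # agrees with the coda estimator up to its O(1/n) correction terms
  ours <- gelman_rubin(good)[["x"]]
  coda_v <- coda::gelman.diag(good, autoburnin = FALSE)$psrf[1, 1]
  expect_lt(abs(ours - coda_v), 0.01)

  expect_error(gelman_rubin(coda::mcmc.list(duplicated_chains()[[1]])),
               "2 chains")
})

test_that("with no data the inclusion machinery recovers its prior", {
  sim <- small_sim()
  T_ <- nrow(sim$counts)
  cmat <- as.data.frame(sim$covariates)
  dat <- list(
    T = T_, sprop = rep(0.03, 5), n1_mean = 800, n1_var = 4000, s2 = 400,
    c_center = 800, c_scale = 200, tau_coef = 1 / 1.5^2, tau_base = 0.01,
    P = cmat$P, S0 = cmat$S0, S1 = cmat$S1, M0 = cmat$M0, M1 = cmat$M1,
    E2 = cmat$E2, E3 = cmat$E3, A = cmat$A, D = cmat$D,
    Isel = rep(NA_real_, 3), Jsel = rep(NA_real_, 10),
    pairs_obs = rep(NA_real_, T_), chicks_obs = rep(NA_real_, T_))
  ms <- build_jags_model(latent = "marginal", predation_missing = FALSE,
                         mass_missing = FALSE, n_surv = 0)
  dr <- run_mcmc(ms, dat, monitor = c("pprod", "Jsel"),
                 control = mcmc_control(seed = 17, chains = 2,
                                        iterations = 8000, thin = 4,
                                        burn_in = 100, adapt = 500))
  M <- do.call(rbind, lapply(dr$samples, as.matrix))
  p1 <- M[, "pprod[1]"]
  ks <- suppressWarnings(ks.test(p1, "punif")$statistic)
  expect_lt(unname(ks), 0.15)
  expect_lt(abs(mean(M[, "Jsel[1]"]) - 0.5), 0.12)
})

test_that("chain order does not affect diagnostics or inclusion", {
  fit <- small_fit()
  rh1 <- gelman_rubin(fit$draws, variables = c("aa0", "b0"))
  rev_draws <- fit$draws
  rev_draws$samples <- coda::mcmc.list(rev(fit$draws$samples))
  rh2 <- gelman_rubin(rev_draws, variables = c("aa0", "b0"))
  expect_equal(rh1, rh2)
  expect_equal(inclusion_probabilities(fit$draws),
               inclusion_probabilities(rev_draws))
})
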