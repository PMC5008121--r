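# The native joint-density implementation probed directly on small
# synthetic problems.

.lj_ingredients <- function(seed = 21) {
  cfg <- scenario_config(n_years = 14, initial_females = 300, s2 = 50,
                         pred_missing = 0, mass_missing = 0,
                         pred_drift_early = 0, survival_window = 5)
  sim <- simulate_scenario(cfg, seed = seed)
  data <- list(counts = sim$counts, covariates = sim$covariates,
               s2 = cfg$s2, c_center = sim$truth$c_center,
               c_scale = sim$truth$c_scale,
               survival = sim$survival,
               sv_error = survival_error_model(sim$survival))
  params <- list(surv = cfg$surv_coef, prod = cfg$prod_coef,
                 p_surv = rep(0.5, 3), p_prod = rep(0.5, 10),
                 V = rep(1e-3, nrow(sim$survival)),
                 Vmax = rep(2e-3, nrow(sim$survival)))
  latent <- list(N = sim$truth$N, chicks = round(sim$truth$chicks))
  list(cfg = cfg, sim = sim, data = data, params = params, latent = latent)
}

test_that("log joint is finite and profiles to a maximum near truth", {
  ing <- .lj_ingredients()
  base <- log_joint(ing$params, ing$latent, ing$data)
  expect_true(is.finite(base))
  expect_named(attr(base, "components"))

  # profile the adult baseline over a grid holding all else at truth:
  # the maximizing grid point should be near the true value
  grid <- seq(ing$cfg$surv_coef$alpha_a0 - 1.5,
              ing$cfg$surv_coef$alpha_a0 + 1.5, length.out = 31)
  prof <- sapply(grid, function(a) {
    p <- ing$params
    p$surv$alpha_a0 <- a
    as.numeric(log_joint(p, ing$latent, ing$data))
  })
  expect_true(all(is.finite(prof)))
  expect_lt(abs(grid[which.max(prof)] - ing$cfg$surv_coef$alpha_a0), 0.5)
})

test_that("worse observations strictly decrease the log joint", {
  ing <- .lj_ingredients()
  base <- as.numeric(log_joint(ing$params, ing$latent, ing$data))
  worse <- ing$data
  # an implausible observation: chick count far above the breeder count
  worse$counts$chicks[3] <- worse$counts$pairs[3] * 4
  expect_lt(as.numeric(log_joint(ing$params, ing$latent, worse)), base)
})

test_that("switch-off equivalence holds in the joint density", {
  # with all indicators 0, covariate coefficient values are irrelevant to
  # every likelihood term (they only move their own priors)
  ing <- .lj_ingredients()
  p0 <- ing$params
  p0$surv$indicators[] <- 0
  p0$prod$indicators[] <- 0
  l1 <- log_joint(p0, ing$latent, ing$data)
  p2 <- p0
  p2$surv$alpha_1 <- 2.2; p2$prod$beta[3] <- -1.7
  l2 <- log_joint(p2, ing$latent, ing$data)
  c1 <- attr(l1, "components"); c2 <- attr(l2, "components")
  expect_equal(c1[c("process", "obs_counts", "obs_survival")],
               c2[c("process", "obs_counts", "obs_survival")])
  expect_false(isTRUE(all.equal(c1[["priors"]], c2[["priors"]])))
})
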