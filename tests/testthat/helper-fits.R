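# Shared fixtures and cached model fits.  Heavy MCMC fits are computed once
# per test run and reused across test files (testthat loads helpers first;
# the acceptance tests, which run first alphabetically, warm the cache).

.fit_cache <- new.env(parent = emptyenv())

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

cached <- function(name, expr) {
  if (!exists(name, .fit_cache)) assign(name, expr, .fit_cache)
  get(name, .fit_cache)
}

# Desk-scale budget used for the study-like fixture fit (the package
# default), and a reduced budget for auxiliary fits in recovery and
# sensitivity checks.
aux_control <- function(seed) {
  mcmc_control(seed = seed, iterations = 20000, thin = 20, burn_in = 300,
               adapt = 1000)
}

micro_control <- function(seed, chains = 2) {
  mcmc_control(seed = seed, chains = chains, iterations = 4000, thin = 10,
               burn_in = 100, adapt = 500)
}

# The packaged study-like fixture and its full-budget fit.
fixture_sim <- function() cached("fixture_sim", study_like_fixture())

fixture_fit <- function() cached("fixture_fit", {
  sim <- fixture_sim()
  sspm(sim$counts, sim$covariates, survival = sim$survival,
       replicates = sim$replicates, control = mcmc_control(seed = 7))
})

# A small, fast scenario for smoke-level fits.
small_config <- function(...) {
  scenario_config(n_years = 14, initial_females = 800,
                  pred_missing = 0, mass_missing = 0,
                  pred_drift_early = 0, survival_window = 5, ...)
}

small_sim <- function(seed = 5) cached(paste0("small_sim_", seed), {
  simulate_scenario(small_config(), seed = seed)
})

small_fit <- function(seed = 5, mseed = 11) {
  cached(paste0("small_fit_", seed, "_", mseed), {
    sim <- small_sim(seed)
    sspm(sim$counts, sim$covariates, survival = sim$survival,
         replicates = sim$replicates, control = micro_control(mseed))
  })
}

# Strong-effects recovery fits (one per replicate seed).
recovery_fit <- function(rep_seed) {
  cached(paste0("recovery_fit_", rep_seed), {
    sim <- simulate_scenario(scenario_strong_effects(), seed = rep_seed)
    sspm(sim$counts, sim$covariates, survival = sim$survival,
         replicates = sim$replicates, control = aux_control(rep_seed + 500))
  })
}

# Predation-dominant scenario fits: full model plus refits with single
# covariates forced out.
pdom_sim <- function() cached("pdom_sim",
  simulate_scenario(scenario_predation_dominant(), seed = 301))

pdom_fit <- function(name, surv_ind = rep(NA_real_, 3),
                     prod_ind = rep(NA_real_, 10)) {
  cached(paste0("pdom_fit_", name), {
    sim <- pdom_sim()
    sspm(sim$counts, sim$covariates, survival = sim$survival,
         replicates = sim$replicates, control = aux_control(97),
         survival_indicators = surv_ind, productivity_indicators = prod_ind)
  })
}

# True parameter vector of a scenario config, in coefficient-table order.
true_params <- function(config) {
  sc <- config$surv_coef; pc <- config$prod_coef
  c(alpha_f0 = sc$alpha_f0, alpha_a0 = sc$alpha_a0,
    alpha_1 = sc$alpha_1, alpha_2 = sc$alpha_2, alpha_3 = sc$alpha_3,
    beta_0 = pc$beta_0,
    stats::setNames(unname(pc$beta), paste0("beta_", 1:10)))
}
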