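# Cached oracle computations shared between the acceptance suite and the
# per-module tests.

# Conjugate sub-model: known integer states, no covariates, uniform prior
# on the adult survival probability.  The posterior of phi_a is then
# Beta(1 + successes, 1 + failures) in closed form; the sampler (exact
# binomial latent-state variant, states supplied as data) must reproduce it.
conjugate_check <- function() cached("conjugate_check", {
  set.seed(77)
  T_ <- 10
  phi_true <- 0.85
  N6 <- integer(T_); N6[1] <- 500L
  S6 <- integer(T_ - 1)
  for (t in 1:(T_ - 1)) {
    S6[t] <- rbinom(1, N6[t], phi_true)
    N6[t + 1] <- S6[t]
  }
  zeros <- rep(0, T_)
  dat <- list(
    T = T_, sprop = rep(0, 5), n1_mean = 500, s2 = 100,
    c_center = 0, c_scale = 1, tau_coef = 1 / 1.5^2,
    P = zeros, S0 = zeros, S1 = zeros, M0 = zeros, M1 = zeros,
    E2 = zeros, E3 = zeros, A = zeros, D = zeros,
    Isel = c(0, 0, 0), Jsel = rep(0, 10),
    pairs_obs = rep(NA_real_, T_), chicks_obs = rep(NA_real_, T_),
    N6 = c(500L, rep(NA_integer_, T_ - 1)),
    Nst = matrix(0L, 5, T_), chick = rep(0L, T_),
    S5 = rep(0L, T_ - 1), S6 = S6)
  ms <- build_jags_model(latent = "binomial", predation_missing = FALSE,
                         mass_missing = FALSE, n_surv = 0,
                         baseline_prior = "uniform")
  dr <- run_mcmc(ms, dat, monitor = "phia",
                 control = mcmc_control(seed = 5, chains = 2,
                                        iterations = 6000, thin = 3,
                                        burn_in = 200, adapt = 500),
                 uniform_baseline_inits = TRUE)
  draws <- do.call(rbind, lapply(dr$samples, as.matrix))[, "phia[1]"]
  succ <- sum(S6); fail <- sum(N6[1:(T_ - 1)] - S6)
  a <- 1 + succ; b <- 1 + fail
  list(draws = draws,
       beta_mean = a / (a + b),
       beta_sd = sqrt(a * b / ((a + b)^2 * (a + b + 1))))
})

# Monte-Carlo check that the stochastic projection's componentwise mean
# equals the deterministic projection, at 20,000 replicates.
mc_consistency_check <- function() cached("mc_consistency", {
  v <- vital_rates(0.4, 0.87, 0.5)
  state <- c(10L, 10L, 10L, 10L, 10L, 200L)
  nrep <- 20000
  acc <- matrix(0, nrep, 6)
  set.seed(99)
  for (i in seq_len(nrep)) acc[i, ] <- project_stochastic(state, v)$state
  list(mean = colMeans(acc), se = apply(acc, 2, sd) / sqrt(nrep),
       expected = project_deterministic(state, v))
})

# mcmc.list with duplicated chains, for the Rhat identity check.
duplicated_chains <- function() {
  set.seed(12)
  ch <- coda::mcmc(matrix(rnorm(600), 300, 2,
                          dimnames = list(NULL, c("x", "y"))))
  coda::mcmc.list(ch, ch, ch)
}
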