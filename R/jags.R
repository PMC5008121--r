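# Generation of the sampler model code and the MCMC driver.
#
# The joint model (demographic process, switch-indicator covariate
# selection, observation and imputation sub-models) is emitted as JAGS model
# code and sampled with rjags.  Three latent-state representations are
# available:
#
#   "marginal"  (default) - the unobserved pre-recruitment stages 1-5 are
#       marginalized exactly: a binomial thinned by a binomial is binomial
#       with the product probability, so the chick cohort of year t enters
#       the breeding class at t + 6 as a single binomial draw with
#       probability phi_f[t] * prod(phi_a[t..t+5]).  Remaining latent nodes
#       (breeders, chicks, recruitment inflow) use a moment-matched normal
#       approximation to the binomial.  This is the fastest and best-mixing
#       representation and leaves the marginal posterior of all monitored
#       quantities unchanged.
#   "full"      - all six stages as latent nodes, normal approximation.
#   "binomial"  - all six stages as integer nodes with exact binomial
#       transitions (for small populations / exactness checks).
#
# A variance floor of 1 (one female^2) keeps the normal-approximation
# precision finite when a latent class empties.

.jags_priors_block <- function(baseline_prior, any_prod_free, latent) {
  base <- if (baseline_prior == "uniform") "
  pf0 ~ dunif(0, 1); af0 <- logit(pf0)
  pa0 ~ dunif(0, 1); aa0 <- logit(pa0)
  pb0 ~ dunif(0, 1); b0  <- logit(pb0)"
  else "
  af0 ~ dnorm(0, tau_base)
  aa0 ~ dnorm(0, tau_base)
  b0  ~ dnorm(0, tau_base)"
  paste0("
  # coefficient slabs, switch indicators and inclusion probabilities", base, "
  a1 ~ dnorm(0, tau_coef)
  a2 ~ dnorm(0, tau_coef)
  a3 ~ dnorm(0, tau_coef)
  for (k in 1:3) {
    Isel[k] ~ dbern(psurv[k])
    psurv[k] ~ dunif(0, 1)
  }
  for (k in 1:10) {
    bb[k] ~ dnorm(0, tau_coef)
    Jsel[k] ~ dbern(pprod[k])
    pprod[k] ~ dunif(0, 1)
  }")
}

.jags_rates_block <- function(mass_missing) {
  paste0(
    if (mass_missing) "
  # arrival mass: missing entries imputed as i.i.d. normal around the
  # observed data (standardized scale)
  for (t in 1:T) { A[t] ~ dnorm(muA, tauA) }" else "", "
  for (t in 1:T) {
    logit(phif[t]) <- af0 + (Isel[1]*a1 + Isel[2]*a2)*P[t] + Isel[3]*a3*S1[t]
    logit(phia[t]) <- aa0 + Isel[1]*a1*P[t] + Isel[3]*a3*S1[t]
    Cc[t] <- (N6[t] - c_center) / c_scale
    logit(b[t]) <- b0 + Jsel[1]*bb[1]*A[t] + Jsel[2]*bb[2]*P[t] +
      Jsel[3]*bb[3]*S0[t] + Jsel[4]*bb[4]*S1[t] + Jsel[5]*bb[5]*M0[t] +
      Jsel[6]*bb[6]*M1[t] + Jsel[7]*bb[7]*E2[t] + Jsel[8]*bb[8]*E3[t] +
      Jsel[9]*bb[9]*D[t] + Jsel[10]*bb[10]*Cc[t]
  }")
}

.jags_walk_block <- function() {
  "
  # backward random walk over the missing predation block, anchored at the
  # earliest observed year; half-normal prior on the innovation sd.
  # Non-centred parameterization (P built from standard-normal innovations
  # scaled by sigma_rw) so the innovation sd and the imputed values do not
  # form a slowly-mixing funnel under componentwise updates.
  sigma_rw ~ dnorm(0, 1 / pow(rw_scale, 2)) T(0,)
  for (j in 1:(k1 - 1)) {
    z_rw[j] ~ dnorm(0, 1)
    P[k1 - j] <- P[k1 - j + 1] + sigma_rw * z_rw[j]
  }"
}

.jags_latent_marginal <- function() {
  "
  # latent demographic process, stages 1-5 marginalized
  N6[1] ~ dnorm(n1_mean, 1 / n1_var) T(1,)
  for (t in 1:T) {
    chick[t] ~ dnorm(N6[t] * b[t] / 2,
                     1 / max(N6[t] * (b[t]/2) * (1 - b[t]/2), 1)) T(0,)
  }
  # inflow of new breeders: initial pre-recruitment stages for years 2-6,
  # then the chick cohort of t - 6 thinned through first-year and five
  # adult-survival transitions
  for (j in 2:6) {
    iprob[j] <- prod(phia[1:(j - 1)])
    rec[j] ~ dnorm(sprop[7 - j] * N6[1] * iprob[j],
                   1 / max(sprop[7 - j] * N6[1] * iprob[j] * (1 - iprob[j]), 1)) T(0,)
  }
  for (t in 7:T) {
    rprob[t] <- phif[t-6] * phia[t-6] * phia[t-5] * phia[t-4] *
                phia[t-3] * phia[t-2] * phia[t-1]
    rec[t] ~ dnorm(chick[t-6] * rprob[t],
                   1 / max(chick[t-6] * rprob[t] * (1 - rprob[t]), 1)) T(0,)
  }
  for (t in 2:T) {
    N6[t] ~ dnorm(N6[t-1] * phia[t-1] + rec[t],
                  1 / max(N6[t-1] * phia[t-1] * (1 - phia[t-1]), 1)) T(1,)
  }"
}

.jags_latent_full <- function() {
  "
  # latent demographic process, all six stages (normal approximation)
  Nst[6, 1] ~ dnorm(n1_mean, 1 / n1_var) T(1,)
  for (s in 1:5) { Nst[s, 1] <- sprop[s] * Nst[6, 1] }
  for (t in 1:T) {
    N6[t] <- Nst[6, t]
    chick[t] ~ dnorm(N6[t] * b[t] / 2,
                     1 / max(N6[t] * (b[t]/2) * (1 - b[t]/2), 1)) T(0,)
  }
  for (t in 1:(T - 1)) {
    Nst[1, t+1] ~ dnorm(chick[t] * phia[t] * phif[t],
        1 / max(chick[t] * phia[t] * phif[t] * (1 - phia[t] * phif[t]), 1)) T(0,)
    for (s in 1:4) {
      Nst[s+1, t+1] ~ dnorm(Nst[s, t] * phia[t],
          1 / max(Nst[s, t] * phia[t] * (1 - phia[t]), 1)) T(0,)
    }
    Nst[6, t+1] ~ dnorm((Nst[5, t] + Nst[6, t]) * phia[t],
        1 / max((Nst[5, t] + Nst[6, t]) * phia[t] * (1 - phia[t]), 1)) T(1,)
  }"
}

.jags_latent_binomial <- function() {
  "
  # latent demographic process, integer states with exact binomial
  # demographic stochasticity
  N6[1] ~ dpois(n1_mean)
  for (s in 1:5) { Nst[s, 1] ~ dpois(max(sprop[s] * n1_mean, 0.01)) }
  for (t in 1:T) {
    chick[t] ~ dbin(b[t] / 2, N6[t])
  }
  for (t in 1:(T - 1)) {
    Nst[1, t+1] ~ dbin(phia[t] * phif[t], chick[t])
    for (s in 1:4) { Nst[s+1, t+1] ~ dbin(phia[t], Nst[s, t]) }
    S5[t] ~ dbin(phia[t], Nst[5, t])
    S6[t] ~ dbin(phia[t], N6[t])
    N6[t+1] <- S5[t] + S6[t]
  }"
}

.jags_obs_block <- function(n_surv, vmax_fixed) {
  paste0("
  # count observation model: common variance on both components
  for (t in 1:T) {
    pairs_obs[t] ~ dnorm(N6[t], 1 / s2)
    chicks_obs[t] ~ dnorm(chick[t], 1 / s2)
  }",
  if (n_surv > 0) paste0("
  # survival observation model: normal error with uniform variance under a
  # stochastic (gamma) ceiling representing the range of reported 95% CIs
  for (j in 1:n_surv) {",
    if (vmax_fixed) "
    V[j] ~ dunif(0, vmax_fix)" else "
    Vmax[j] ~ dgamma(v_shape, v_rate)
    V[j] ~ dunif(0, Vmax[j])", "
    sv_mean[j] <- equals(sv_class[j], 1) * phif[sv_year[j]] +
                  equals(sv_class[j], 2) * phia[sv_year[j]]
    sv_est[j] ~ dnorm(sv_mean[j], 1 / (V[j] + 1e-8))
  }") else "")
}

#' Emit the sampler model code for the state-space model
#'
#' Assembles the JAGS model description from the process, observation,
#' selection and imputation sub-models.  Normally called by [sspm()].
#'
#' @param latent latent-state representation: `"marginal"` (pre-recruitment
#'   stages marginalized exactly; default), `"full"` (all six stages,
#'   normal approximation), or `"binomial"` (integer states, exact).
#' @param predation_missing does the predation series have a missing initial
#'   block (adds the backward random-walk imputation)?
#' @param mass_missing does arrival mass have missing entries?
#' @param n_surv number of survival observations (0 drops that block).
#' @param vmax_fixed use a fixed variance ceiling for survival errors
#'   (degenerate gamma moment match)?
#' @param baseline_prior `"normal"` (diffuse normal on baseline logits) or
#'   `"uniform"` (uniform on the probability scale).
#' @return a single string of model code.
#' @export
build_jags_model <- function(latent = c("marginal", "full", "binomial"),
                             predation_missing = TRUE, mass_missing = TRUE,
                             n_surv = 1, vmax_fixed = FALSE,
                             baseline_prior = c("normal", "uniform")) {
  latent <- match.arg(latent)
  baseline_prior <- match.arg(baseline_prior)
  latent_block <- switch(latent,
    marginal = .jags_latent_marginal(),
    full = .jags_latent_full(),
    binomial = .jags_latent_binomial())
  paste0("model {",
         .jags_priors_block(baseline_prior),
         if (predation_missing) .jags_walk_block() else "",
         .jags_rates_block(mass_missing),
         latent_block,
         .jags_obs_block(n_surv, vmax_fixed),
         "\n}\n")
}

#' MCMC configuration
#'
#' @param seed master integer seed (mandatory: reproducibility is part of
#'   the model contract).  Per-chain RNG seeds and overdispersed initial
#'   values are derived from it.
#' @param chains number of chains (>= 2 so convergence can be diagnosed).
#' @param iterations sampling iterations per chain (after burn-in).
#' @param thin thinning interval; `iterations / thin` draws are retained.
#' @param burn_in number of post-thinning draws discarded as burn-in (the
#'   sampler runs `burn_in * thin` burn-in iterations).
#' @param adapt adaptation iterations for the sampler tuning phase.
#' @return list of class `mcmc_control`.
#' @export
mcmc_control <- function(seed, chains = 3, iterations = 60000, thin = 30,
                         burn_in = 1300, adapt = 2000) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop_sspm("mcmc_control: an integer seed is required; ",
              "MCMC runs must be reproducible")
  stopifnot(chains >= 2, iterations >= thin, thin >= 1, burn_in >= 0)
  structure(list(seed = as.integer(seed), chains = as.integer(chains),
                 iterations = as.integer(iterations), thin = as.integer(thin),
                 burn_in = as.integer(burn_in), adapt = as.integer(adapt)),
            class = "mcmc_control")
}

# Overdispersed parameter inits and chain RNG seeds derived from the master
# seed.
.chain_inits <- function(control) {
  lapply(seq_len(control$chains), function(i) {
    with_seed(control$seed * 131L + i, {
      list(af0 = stats::rnorm(1, 0, 1),
           aa0 = stats::rnorm(1, 1.5, 1),
           b0 = stats::rnorm(1, 0, 1),
           a1 = stats::rnorm(1, 0, 0.5),
           a2 = stats::rnorm(1, 0, 0.5),
           a3 = stats::rnorm(1, 0, 0.5),
           bb = stats::rnorm(10, 0, 0.5),
           .RNG.name = "base::Mersenne-Twister",
           .RNG.seed = control$seed * 1009L %% 2147483L + i)
    })
  })
}

#' Run the MCMC sampler
#'
#' Compiles the model, runs adaptation and burn-in, then draws thinned
#' samples from every chain.  Chains are initialized at overdispersed
#' points in parameter space with chain-specific RNG seeds, so runs with
#' identical control settings are bit-for-bit reproducible.
#'
#' @param model_string model code from [build_jags_model()].
#' @param data named list of data nodes.
#' @param monitor character vector of node names to record.
#' @param control an [mcmc_control()] object.
#' @param inits optional list of per-chain initial values; defaults to
#'   overdispersed values derived from `control$seed`.
#' @param uniform_baseline_inits drop logit-scale baseline inits (used with
#'   `baseline_prior = "uniform"`).
#' @return object of class `posterior_draws`: list with `samples` (a
#'   [coda::mcmc.list]), `control`, `monitor`, `elapsed` (seconds).
#' @export
run_mcmc <- function(model_string, data, monitor, control,
                     inits = NULL, uniform_baseline_inits = FALSE) {
  stopifnot(inherits(control, "mcmc_control"))
  if (is.null(inits)) {
    inits <- .chain_inits(control)
    if (uniform_baseline_inits)
      inits <- lapply(inits, function(z) z[setdiff(names(z),
                                                   c("af0", "aa0", "b0"))])
  }
  t0 <- Sys.time()
  rjags::load.module("glm", quiet = TRUE)
  m <- tryCatch(
    rjags::jags.model(textConnection(model_string), data = data,
                      inits = inits, n.chains = control$chains,
                      n.adapt = control$adapt, quiet = TRUE),
    error = function(e) stop_sspm("MCMC initialization failed: ",
                                  conditionMessage(e)))
  if (control$burn_in > 0)
    stats::update(m, control$burn_in * control$thin)
  samples <- tryCatch(
    rjags::coda.samples(m, variable.names = monitor,
                        n.iter = control$iterations, thin = control$thin),
    error = function(e) stop_sspm("MCMC sampling failed: ",
                                  conditionMessage(e)))
  bad <- vapply(samples, function(ch) any(!is.finite(as.matrix(ch))), TRUE)
  if (any(bad))
    stop_sspm("MCMC produced non-finite draws in chain(s) ",
              paste(which(bad), collapse = ", "),
              "; check data scaling and priors")
  structure(list(samples = samples, control = control, monitor = monitor,
                 elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  n <- nrow(x$samples[[1]])
  cat("Posterior draws:", length(x$samples), "chains x", n,
      "retained draws (thin", x$control$thin, "),",
      sprintf("%.1f s\n", x$elapsed))
  invisible(x)
}

# Stack all chains into one matrix.
draws_matrix <- function(draws) {
  s <- if (inherits(draws, "posterior_draws")) draws$samples else draws
  do.call(rbind, lapply(s, as.matrix))
}
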