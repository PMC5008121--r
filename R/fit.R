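# Model fitting: the user-facing sspm() function and its S3 methods.

#' Prior settings
#'
#' Weakly informative defaults: covariate coefficients Normal(0, 1.5^2) on
#' the logit scale (roughly uniform on the probability scale once mapped
#' through the inverse logit), baseline logits Normal(0, 10^2), inclusion
#' probabilities Uniform(0, 1), and an initial breeding-female abundance
#' centred on the first observed count with variance `n1_var_mult * s2`.
#'
#' @param coef_sd prior sd of covariate coefficients (logit scale).
#' @param baseline_sd prior sd of baseline logits.
#' @param n1_var_mult multiplier of the count observation variance used for
#'   the initial-abundance prior variance.
#' @return list of class `sspm_priors`.
#' @export
sspm_priors <- function(coef_sd = 1.5, baseline_sd = 10, n1_var_mult = 10) {
  structure(list(coef_sd = coef_sd, baseline_sd = baseline_sd,
                 n1_var_mult = n1_var_mult), class = "sspm_priors")
}

# Rates used only to initialize the pre-recruitment stage structure
# (typical crested-penguin values; the data update everything else).
.init_rates <- function() vital_rates(phi_f = 0.4, phi_a = 0.85, b = 0.5)

# Map survival age_class labels to model indices.
.sv_class_index <- function(x) {
  i <- match(x, c("fledgling", "older"))
  if (anyNA(i))
    stop_sspm("survival age_class must be 'fledgling' or 'older'")
  i
}

#' Fit the age-structured state-space population model
#'
#' Fits the joint Bayesian model: a six-stage female-only demographic
#' process with binomial demographic stochasticity, logit-linear survival
#' and productivity functions whose covariate effects are gated by Bernoulli
#' switch indicators (stochastic search variable selection), normal
#' observation error on breeding-pair and chick counts, a hierarchical
#' error model for mark-recapture survival estimates, and in-sampler
#' imputation of missing covariate segments (i.i.d. normal for arrival
#' mass, a backward random walk for the predation index).
#'
#' @param counts data.frame with columns `year`, `pairs` (breeding pairs =
#'   breeding females) and `chicks` (total chicks fledged; the model works
#'   with female chicks, `chicks / 2`).
#' @param covariates a [covariate_matrix()], or a raw data.frame accepted by
#'   that constructor (may include lag lead-in years).
#' @param survival optional data.frame of mark-recapture survival estimates
#'   (`year`, `age_class`, `estimate`, `ci_low`, `ci_high`); may cover only
#'   a sub-window of years.  Years without survival data are informed only
#'   by counts and covariates through the process model.
#' @param control an [mcmc_control()] object (a seed is mandatory).
#' @param replicates optional data.frame of repeated censuses (`year`,
#'   `count`) from which the count observation variance is estimated via
#'   [repeated_count_variance()].
#' @param s2 count observation variance, overriding / replacing
#'   `replicates`.
#' @param survival_indicators,productivity_indicators numeric vectors
#'   (length 3 and 10) controlling the switch indicators: `NA` = estimated
#'   (default), `0`/`1` = forced.  Forcing an indicator to 0 refits the
#'   model with that covariate excluded from every iteration, as used by
#'   the sensitivity analysis.
#' @param latent latent-state representation, see [build_jags_model()].
#' @param baseline_prior prior family for the baseline logits.
#' @param priors an [sspm_priors()] object.
#' @return object of class `sspm` with components `draws`
#'   ([run_mcmc()] output), `coefficients` (posterior summary table),
#'   `inclusion` (posterior inclusion probabilities), `states`, `rates`
#'   (annual posterior summaries), `imputations`, `data`, `control`.
#' @seealso [summary.sspm()], [gelman_rubin()], [inclusion_probabilities()],
#'   [validate_without_data()], [covariate_sensitivity()]
#' @export
sspm <- function(counts, covariates, survival = NULL, control,
                 replicates = NULL, s2 = NULL,
                 survival_indicators = rep(NA_real_, 3),
                 productivity_indicators = rep(NA_real_, 10),
                 latent = c("marginal", "full", "binomial"),
                 baseline_prior = c("normal", "uniform"),
                 priors = sspm_priors()) {
  latent <- match.arg(latent)
  baseline_prior <- match.arg(baseline_prior)
  stopifnot(inherits(control, "mcmc_control"))
  need <- c("year", "pairs", "chicks")
  if (!all(need %in% names(counts)))
    stop_sspm("counts needs columns: ", paste(need, collapse = ", "))
  counts <- counts[order(counts$year), ]
  T_ <- nrow(counts)
  if (T_ < 10) stop_sspm("need at least 10 years of counts")
  years <- counts$year

  if (!inherits(covariates, "covariate_matrix"))
    covariates <- covariate_matrix(covariates, years = years)
  if (!identical(as.integer(covariates$year), as.integer(years)))
    stop_sspm("covariate years must match count years exactly")

  # count observation variance
  if (is.null(s2)) {
    if (is.null(replicates))
      stop_sspm("supply either `replicates` (repeated censuses) or `s2`")
    s2 <- repeated_count_variance(replicates)
  }
  if (s2 <= 0) stop_sspm("s2 must be positive")

  # completeness: only P (leading block) and A may be missing
  mask <- covariate_mask(covariates)
  for (vn in c("S0", "S1", "M0", "M1", "E2", "E3", "D")) {
    if (any(!mask[, vn]))
      stop_sspm("covariate column ", vn, " has missing values in year(s) ",
                paste(years[!mask[, vn]], collapse = ", "),
                "; only P (leading block) and A can be imputed")
  }
  p_obs <- mask[, "P"]
  predation_missing <- any(!p_obs)
  k1 <- if (predation_missing) {
    k <- which(p_obs)[1]
    if (is.na(k) || !all(p_obs[k:T_]) || any(p_obs[seq_len(k - 1)]))
      stop_sspm("P missingness must be one contiguous leading block")
    k
  } else 1L
  mass_missing <- any(!mask[, "A"])

  # survival observations and their error model
  n_surv <- if (is.null(survival)) 0L else nrow(survival)
  sv_err <- NULL
  if (n_surv > 0) {
    if (!all(survival$year %in% years))
      stop_sspm("survival years outside the count series")
    sv_err <- survival_error_model(survival)
  }

  c_center <- mean(counts$pairs)
  c_scale <- stats::sd(counts$pairs)
  sprop <- stable_stage_proportions(.init_rates())[1:5]

  dat <- list(
    T = T_,
    pairs_obs = counts$pairs,
    chicks_obs = counts$chicks / 2,
    s2 = s2,
    c_center = c_center, c_scale = c_scale,
    sprop = sprop,
    n1_mean = counts$pairs[1],
    n1_var = priors$n1_var_mult * s2,
    tau_coef = 1 / priors$coef_sd^2,
    P = covariates$P, S0 = covariates$S0, S1 = covariates$S1,
    M0 = covariates$M0, M1 = covariates$M1,
    E2 = covariates$E2, E3 = covariates$E3,
    A = covariates$A, D = covariates$D,
    Isel = as.numeric(survival_indicators),
    Jsel = as.numeric(productivity_indicators)
  )
  if (baseline_prior == "normal") dat$tau_base <- 1 / priors$baseline_sd^2
  if (predation_missing) {
    dat$k1 <- k1
    dat$rw_scale <- stats::sd(diff(covariates$P[k1:T_]))
  }
  if (mass_missing) { dat$muA <- 0; dat$tauA <- 1 }
  if (n_surv > 0) {
    dat$n_surv <- n_surv
    dat$sv_est <- survival$estimate
    dat$sv_year <- match(survival$year, years)
    dat$sv_class <- .sv_class_index(survival$age_class)
    if (sv_err$degenerate) dat$vmax_fix <- sv_err$fixed_vmax
    else { dat$v_shape <- sv_err$shape; dat$v_rate <- sv_err$rate }
  }

  model_string <- build_jags_model(
    latent = latent, predation_missing = predation_missing,
    mass_missing = mass_missing, n_surv = n_surv,
    vmax_fixed = isTRUE(sv_err$degenerate), baseline_prior = baseline_prior)

  monitor <- c("af0", "aa0", "a1", "a2", "a3", "b0", "bb",
               "Isel", "Jsel", "psurv", "pprod",
               "N6", "chick", "phif", "phia", "b")
  if (predation_missing) monitor <- c(monitor, "sigma_rw", "P")
  if (mass_missing) monitor <- c(monitor, "A")

  # start every chain's latent states at data-consistent values so the
  # overdispersed parameter inits cannot strand a chain in a remote mode
  latent_inits <- local({
    n6 <- pmax(counts$pairs, 2)
    ck <- pmax(counts$chicks / 2, 1)
    switch(latent,
      marginal = list(N6 = n6, chick = ck),
      full = {
        Nst <- rbind(t(vapply(sprop, function(p) p * n6, numeric(T_))), n6)
        Nst[1:5, 1] <- NA  # deterministic at t = 1
        dimnames(Nst) <- NULL
        list(Nst = Nst, chick = ck)
      },
      binomial = NULL)
  })
  if (predation_missing && !is.null(latent_inits)) {
    # flat walk start: imputed predation begins at the anchor value
    latent_inits$z_rw <- rep(0, k1 - 1)
    latent_inits$sigma_rw <- dat$rw_scale
  }
  inits <- lapply(.chain_inits(control), function(z) {
    if (baseline_prior == "uniform")
      z <- z[setdiff(names(z), c("af0", "aa0", "b0"))]
    c(z, latent_inits)
  })
  draws <- run_mcmc(model_string, dat, monitor, control, inits = inits)

  fit <- structure(list(
    draws = draws,
    data = list(counts = counts, covariates = covariates,
                survival = survival, s2 = s2, years = years, k1 = k1,
                c_center = c_center, c_scale = c_scale, sprop = sprop,
                predation_missing = predation_missing,
                mass_missing = mass_missing, sv_error = sv_err),
    control = control, latent = latent, baseline_prior = baseline_prior,
    priors = priors, model_string = model_string,
    indicators = list(survival = survival_indicators,
                      productivity = productivity_indicators),
    call = match.call()
  ), class = "sspm")
  fit$coefficients <- .coef_table(fit)
  fit$inclusion <- inclusion_probabilities(fit)
  fit$states <- .state_table(fit)
  fit$rates <- .rate_table(fit)
  fit
}

# names of scalar coefficient nodes
.COEF_NODES <- c("af0", "aa0", "a1", "a2", "a3", "b0", paste0("bb[", 1:10, "]"))
.COEF_LABELS <- c("alpha_f0", "alpha_a0", "alpha_1", "alpha_2", "alpha_3",
                  "beta_0", paste0("beta_", 1:10))

.coef_table <- function(fit) {
  M <- draws_matrix(fit$draws)
  nodes <- intersect(c(.COEF_NODES, "sigma_rw"), colnames(M))
  qs <- t(apply(M[, nodes, drop = FALSE], 2, stats::quantile,
                c(0.025, 0.5, 0.975)))
  rh <- gelman_rubin(fit$draws, variables = nodes)
  out <- data.frame(parameter = c(.COEF_LABELS, "sigma_rw")[
                      match(nodes, c(.COEF_NODES, "sigma_rw"))],
                    mean = colMeans(M[, nodes, drop = FALSE]),
                    sd = apply(M[, nodes, drop = FALSE], 2, stats::sd),
                    q2.5 = qs[, 1], median = qs[, 2], q97.5 = qs[, 3],
                    rhat = rh[nodes], row.names = nodes)
  out
}

.annual_table <- function(fit, node) {
  M <- draws_matrix(fit$draws)
  cols <- paste0(node, "[", seq_along(fit$data$years), "]")
  cols <- cols[cols %in% colnames(M)]
  qs <- t(apply(M[, cols, drop = FALSE], 2, stats::quantile,
                c(0.025, 0.5, 0.975)))
  data.frame(year = fit$data$years[seq_along(cols)],
             mean = colMeans(M[, cols, drop = FALSE]),
             q2.5 = qs[, 1], median = qs[, 2], q97.5 = qs[, 3],
             row.names = NULL)
}

.state_table <- function(fit) {
  list(breeders = .annual_table(fit, "N6"),
       chicks = .annual_table(fit, "chick"))
}

.rate_table <- function(fit) {
  list(phi_f = .annual_table(fit, "phif"),
       phi_a = .annual_table(fit, "phia"),
       b = .annual_table(fit, "b"))
}

#' Posterior inclusion probabilities of the switch indicators
#'
#' The posterior mean of each Bernoulli inclusion indicator: the estimated
#' probability that the covariate operates in the model.  A covariate with
#' probability above 0.5 is included in more than half of all model
#' parameterizations visited by the sampler.
#'
#' @param x an `sspm` fit or a `posterior_draws` object.
#' @return named numeric vector over the 3 survival and 10 productivity
#'   indicators.
#' @export
inclusion_probabilities <- function(x) {
  M <- draws_matrix(if (inherits(x, "sspm")) x$draws else x)
  nodes <- c(paste0("Isel[", 1:3, "]"), paste0("Jsel[", 1:10, "]"))
  nodes <- intersect(nodes, colnames(M))
  p <- colMeans(M[, nodes, drop = FALSE])
  names(p) <- c(paste0("surv.", SURV_TERMS),
                paste0("prod.", PROD_TERMS))[
    match(nodes, c(paste0("Isel[", 1:3, "]"), paste0("Jsel[", 1:10, "]")))]
  p
}

#' Gelman-Rubin potential scale reduction statistic
#'
#' Between/within-chain variance diagnostic.  For each monitored quantity,
#' with m chains of n draws, within-chain variance W and between-chain
#' variance of the chain means Bm, the statistic is
#' `Rhat = sqrt((W + (1 + 1/m) * Bm) / W)`.  Chains that are exact copies
#' give exactly 1; values near 1 signal convergence.  (The pooled-variance
#' term omits the (n-1)/n deflation so the identical-chain case is exact;
#' the difference from the textbook estimator is O(1/n) and conservative.)
#'
#' @param x an `sspm` fit, `posterior_draws`, or [coda::mcmc.list].
#' @param variables optional character vector restricting the computation.
#' @return named vector of Rhat values.
#' @export
gelman_rubin <- function(x, variables = NULL) {
  s <- if (inherits(x, "sspm")) x$draws$samples
       else if (inherits(x, "posterior_draws")) x$samples
       else x
  if (!coda::is.mcmc.list(s)) s <- coda::as.mcmc.list(s)
  m <- length(s)
  if (m < 2) stop_sspm("gelman_rubin: need at least 2 chains")
  n <- nrow(s[[1]])
  if (n < 10) stop_sspm("gelman_rubin: need at least 10 draws per chain")
  mats <- lapply(s, as.matrix)
  if (!is.null(variables))
    mats <- lapply(mats, function(M) M[, variables, drop = FALSE])
  W <- Reduce(`+`, lapply(mats, function(M) apply(M, 2, stats::var))) / m
  means <- do.call(rbind, lapply(mats, colMeans))
  Bm <- apply(means, 2, stats::var)
  const <- W == 0 & Bm == 0   # constant (e.g. forced) quantities
  rh <- sqrt((W + (1 + 1 / m) * Bm) / W)
  rh[const] <- 1
  rh
}

#' Rhat over all monitored quantities of a fit
#'
#' Computes the Gelman-Rubin statistic for the monitored set: all
#' coefficients, the inclusion probabilities p, variance-related
#' hyperparameters, and the latent breeding-female abundances.
#'
#' @param fit an `sspm` object.
#' @return named vector of Rhat values.
#' @export
monitored_rhat <- function(fit) {
  stopifnot(inherits(fit, "sspm"))
  M <- colnames(draws_matrix(fit$draws))
  want <- c(.COEF_NODES,
            paste0("psurv[", 1:3, "]"), paste0("pprod[", 1:10, "]"),
            "sigma_rw",
            grep("^N6\\[", M, value = TRUE))
  gelman_rubin(fit$draws, variables = intersect(want, M))
}

# ---- S3 methods ----------------------------------------------------------

#' @export
print.sspm <- function(x, ...) {
  cat("Age-structured state-space population model fit\n")
  cat(sprintf("  %d years (%d-%d), %d survival obs, s2 = %.1f\n",
              length(x$data$years), min(x$data$years), max(x$data$years),
              if (is.null(x$data$survival)) 0L else nrow(x$data$survival),
              x$data$s2))
  cat(sprintf("  %d chains x %d draws (thin %d), %.0f s; max Rhat = %.3f\n",
              x$control$chains,
              nrow(x$draws$samples[[1]]), x$control$thin, x$draws$elapsed,
              max(monitored_rhat(x))))
  cat("\nCoefficients (posterior mean [95% CrI]):\n")
  cf <- x$coefficients
  for (i in seq_len(nrow(cf)))
    cat(sprintf("  %-10s %8.3f [%7.3f, %7.3f]\n", cf$parameter[i],
                cf$mean[i], cf$q2.5[i], cf$q97.5[i]))
  cat("\nInclusion probabilities > 0.5:\n  ")
  p <- x$inclusion[x$inclusion > 0.5]
  if (length(p)) cat(paste(sprintf("%s=%.2f", names(p), p), collapse = ", "))
  else cat("(none)")
  cat("\n")
  invisible(x)
}

#' @export
summary.sspm <- function(object, ...) {
  out <- list(coefficients = object$coefficients,
              inclusion = object$inclusion,
              rhat_max = max(monitored_rhat(object)),
              states = object$states, rates = object$rates,
              s2 = object$data$s2, years = object$data$years)
  class(out) <- "summary.sspm"
  out
}

#' @export
print.summary.sspm <- function(x, ...) {
  cat("Coefficient posterior summary:\n")
  print(round(x$coefficients[, -1], 3))
  cat("\nInclusion probabilities:\n")
  print(round(x$inclusion, 3))
  cat(sprintf("\nMax Rhat over monitored quantities: %.3f\n", x$rhat_max))
  invisible(x)
}

#' @export
coef.sspm <- function(object, ...) {
  stats::setNames(object$coefficients$mean, object$coefficients$parameter)
}

#' @export
fitted.sspm <- function(object, ...) {
  stats::setNames(object$states$breeders$median, object$data$years)
}

#' Residuals of the count observation model
#'
#' Observed breeding-pair counts minus the posterior median latent
#' breeding-female abundance.
#'
#' @param object an `sspm` fit.
#' @param ... unused.
#' @export
residuals.sspm <- function(object, ...) {
  stats::setNames(object$data$counts$pairs - object$states$breeders$median,
                  object$data$years)
}

#' Posterior summaries of latent states or vital rates
#'
#' @param object an `sspm` fit.
#' @param type `"abundance"` (breeding females and chicks) or `"rates"`
#'   (annual phi_f, phi_a, b).
#' @param ... unused.
#' @return data.frame(s) of annual posterior summaries.
#' @export
predict.sspm <- function(object, type = c("abundance", "rates"), ...) {
  type <- match.arg(type)
  if (type == "abundance") object$states else object$rates
}

#' Simulate population trajectories from the fitted model
#'
#' Draws joint posterior parameter samples and simulates the stochastic
#' demographic process forward from the initial state, including count
#' observation noise - the posterior-predictive trajectory ensemble.
#'
#' @param object an `sspm` fit.
#' @param nsim number of trajectories.
#' @param seed integer seed.
#' @param marginal sample parameters independently from their marginal
#'   posteriors (as in [validate_without_data()]) instead of jointly.
#' @param ... unused.
#' @return matrix (`nsim` x years) of simulated observed breeding-female
#'   counts.
#' @export
simulate.sspm <- function(object, nsim = 500, seed = NULL, marginal = FALSE,
                          ...) {
  ens <- .simulate_ensemble(object, n_sim = nsim, seed = seed,
                            marginal = marginal, shuffle = FALSE)
  ens$pairs_obs
}

#' Plot the fitted population trajectory
#'
#' Observed breeding-pair counts with the posterior median and 95% credible
#' band of the latent breeding-female abundance.
#'
#' @param x an `sspm` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sspm <- function(x, ...) {
  st <- x$states$breeders
  yl <- range(st$q2.5, st$q97.5, x$data$counts$pairs)
  graphics::plot(st$year, st$median, type = "l", lwd = 2,
                 ylim = yl, xlab = "year", ylab = "breeding females", ...)
  graphics::polygon(c(st$year, rev(st$year)), c(st$q2.5, rev(st$q97.5)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::points(x$data$counts$year, x$data$counts$pairs, pch = 19)
  invisible(x)
}
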