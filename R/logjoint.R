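# Native evaluation of the joint log density.
#
# This is an independent, direct R implementation of the same joint model
# the sampler draws from, over exact integer latent states (binomial
# process terms rather than the sampler's normal approximation).  It exists
# so the model's density can be probed directly - profile checks, grid
# searches, unit tests - without going through MCMC.

# log pmf of the sum of two independent binomials (exact convolution)
.dbinom_sum_log <- function(x, n1, p1, n2, p2) {
  if (x < 0 || x > n1 + n2) return(-Inf)
  k <- max(0, x - n2):min(n1, x)
  m <- stats::dbinom(k, n1, p1, log = TRUE) +
    stats::dbinom(x - k, n2, p2, log = TRUE)
  mx <- max(m)
  if (!is.finite(mx)) return(-Inf)
  mx + log(sum(exp(m - mx)))
}

#' Joint log density of parameters, latent states and data
#'
#' Evaluates the full joint density: binomial process terms for every stage
#' transition and for chick production, the count and survival observation
#' terms, coefficient and indicator priors, and the imputation terms for
#' missing covariates.  Latent states are exact integers here; the
#' unnormalized log density is returned with a per-component breakdown.
#'
#' @param params list with elements `surv` ([survival_coefficients()]),
#'   `prod` ([productivity_coefficients()]), `p_surv` (3 inclusion
#'   probabilities), `p_prod` (10), and optionally `V`, `Vmax` (per
#'   survival-observation error variances and ceilings), `sigma_rw`
#'   (random-walk sd), `imputed_P`, `imputed_A` (values for the missing
#'   cells, chronological order).
#' @param latent list with `N` (6 x T integer matrix of stage abundances)
#'   and `chicks` (length-T integer vector of realized female chicks).
#' @param data list with `counts` (data.frame `year`, `pairs`, `chicks` on
#'   the raw scale), `covariates` (a [covariate_matrix()]; missing cells
#'   are filled from `params$imputed_*`), `s2`, `c_center`, `c_scale`, and
#'   optionally `survival` (observations) with `sv_error` (a
#'   [survival_error_model()]), `rw_scale` (half-normal prior scale).
#' @param priors an [sspm_priors()] object.
#' @return scalar log density with attribute `components` (named vector).
#'   An error names the offending component if any term is non-finite with
#'   finite inputs expected.
#' @export
log_joint <- function(params, latent, data, priors = sspm_priors()) {
  N <- latent$N
  chicks <- latent$chicks
  T_ <- ncol(N)
  stopifnot(nrow(N) == 6, length(chicks) == T_,
            nrow(data$covariates) == T_)
  cov <- as.data.frame(data$covariates)
  # fill imputed covariate cells
  if (!is.null(params$imputed_P)) {
    miss <- which(is.na(cov$P))
    stopifnot(length(params$imputed_P) == length(miss))
    cov$P[miss] <- params$imputed_P
  }
  if (!is.null(params$imputed_A)) {
    miss <- which(is.na(cov$A))
    stopifnot(length(params$imputed_A) == length(miss))
    cov$A[miss] <- params$imputed_A
  }

  comp <- c(process = 0, obs_counts = 0, obs_survival = 0, priors = 0,
            imputation = 0)

  # vital rates per year
  phif <- phia <- b <- numeric(T_)
  for (t in seq_len(T_)) {
    sr <- survival_rates(params$surv, cov[t, ])
    phif[t] <- sr["phi_f"]; phia[t] <- sr["phi_a"]
    Ct <- (N[6, t] - data$c_center) / data$c_scale
    b[t] <- productivity_rate(params$prod, cov[t, ], Ct)
  }

  # process terms
  for (t in seq_len(T_)) {
    comp["process"] <- comp["process"] +
      stats::dbinom(chicks[t], N[6, t], b[t] / 2, log = TRUE)
    if (t < T_) {
      comp["process"] <- comp["process"] +
        stats::dbinom(N[1, t + 1], chicks[t], phia[t] * phif[t], log = TRUE) +
        sum(stats::dbinom(N[2:5, t + 1], N[1:4, t], phia[t], log = TRUE)) +
        .dbinom_sum_log(N[6, t + 1], N[5, t], phia[t], N[6, t], phia[t])
    }
  }

  # observation terms
  comp["obs_counts"] <- count_loglik(N[6, ], chicks,
                                     data$counts$pairs,
                                     data$counts$chicks / 2, data$s2)
  if (!is.null(data$survival) && nrow(data$survival) > 0) {
    sv <- data$survival
    idx <- match(sv$year, data$counts$year)
    mu <- ifelse(.sv_class_index(sv$age_class) == 1, phif[idx], phia[idx])
    V <- params$V
    Vmax <- params$Vmax
    stopifnot(length(V) == nrow(sv), length(Vmax) == nrow(sv))
    em <- data$sv_error
    comp["obs_survival"] <-
      sum(stats::dnorm(sv$estimate, mu, sqrt(V), log = TRUE)) +
      sum(stats::dunif(V, 0, Vmax, log = TRUE)) +
      if (isTRUE(em$degenerate)) 0 else
        sum(stats::dgamma(Vmax, em$shape, em$rate, log = TRUE))
  }

  # priors
  sc <- params$surv; pc <- params$prod
  comp["priors"] <-
    sum(stats::dnorm(c(sc$alpha_f0, sc$alpha_a0, pc$beta_0),
                     0, priors$baseline_sd, log = TRUE)) +
    sum(stats::dnorm(c(sc$alpha_1, sc$alpha_2, sc$alpha_3, pc$beta),
                     0, priors$coef_sd, log = TRUE)) +
    sum(stats::dbinom(sc$indicators, 1, params$p_surv, log = TRUE)) +
    sum(stats::dbinom(pc$indicators, 1, params$p_prod, log = TRUE))

  # imputation terms
  if (!is.null(params$imputed_A))
    comp["imputation"] <- comp["imputation"] +
      sum(stats::dnorm(params$imputed_A, 0, 1, log = TRUE))
  if (!is.null(params$imputed_P)) {
    k1 <- length(params$imputed_P) + 1
    walk <- c(params$imputed_P, cov$P[k1])  # chronological incl. anchor
    comp["imputation"] <- comp["imputation"] +
      sum(stats::dnorm(diff(walk), 0, params$sigma_rw, log = TRUE)) +
      stats::dnorm(params$sigma_rw, 0, data$rw_scale, log = TRUE) + log(2)
  }

  bad <- names(comp)[is.nan(comp)]
  if (length(bad))
    stop_sspm("log_joint: non-finite contribution from component(s): ",
              paste(bad, collapse = ", "))
  structure(sum(comp), components = comp)
}
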