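# Observation models: count error variance from repeated censuses, count
# likelihood, and the hierarchical error model for mark-recapture survival
# estimates.

#' Count observation variance from repeated censuses
#'
#' The count observation variance is the mean over replicated years of the
#' within-year variance of repeat censuses, divided by the mean number of
#' replicates per year (the variance of a yearly count estimate formed as
#' the mean of its replicates).  It is returned on whatever scale the counts
#' are supplied in; the same variance is applied to all years of the count
#' likelihood.
#'
#' @param replicates data.frame with columns `year` and `count`, one row per
#'   repeat census.  Years with fewer than 2 replicates are ignored for the
#'   variance but counted in the mean number of replicates only if they have
#'   at least 2.
#' @return scalar `s2`.
#' @export
repeated_count_variance <- function(replicates) {
  stopifnot(all(c("year", "count") %in% names(replicates)))
  spl <- split(replicates$count, replicates$year)
  spl <- spl[vapply(spl, length, 1L) >= 2]
  if (!length(spl))
    stop_sspm("repeated_count_variance: no year has >= 2 replicate counts; ",
              "supply the count observation variance s2 directly")
  sigma2_bar <- mean(vapply(spl, stats::var, 1))
  n_bar <- mean(vapply(spl, length, 1L))
  sigma2_bar / n_bar
}

#' Count observation log-likelihood
#'
#' Normal observation error on the breeding-female count and the female
#' chick count, each centred on the latent value with common variance `s2`.
#'
#' @param latent_pairs,latent_chicks latent breeding females and realized
#'   female chicks (vectors over years).
#' @param obs_pairs,obs_chicks observed counts on the same (female) scale;
#'   `NA` entries contribute nothing.
#' @param s2 count observation variance (> 0).
#' @return total log density.
#' @export
count_loglik <- function(latent_pairs, latent_chicks, obs_pairs, obs_chicks,
                         s2) {
  if (!is.finite(s2) || s2 <= 0)
    stop_sspm("count_loglik: s2 must be positive")
  ll <- function(lat, obs) {
    ok <- !is.na(obs)
    sum(stats::dnorm(obs[ok], lat[ok], sqrt(s2), log = TRUE))
  }
  ll(latent_pairs, obs_pairs) + ll(latent_chicks, obs_chicks)
}

#' Variance implied by a 95% confidence interval
#'
#' Converts a symmetric normal 95% CI to the implied sampling variance,
#' `(half-width / 1.96)^2`.  Asymmetric intervals use the larger half-width
#' (conservative).
#'
#' @param estimate point estimate.
#' @param ci_low,ci_high 95% CI bounds.
#' @return implied variance.
#' @export
ci_implied_variance <- function(estimate, ci_low, ci_high) {
  if (any(ci_high <= ci_low))
    stop_sspm("ci_implied_variance: degenerate CI (ci_high <= ci_low)")
  hw <- pmax(estimate - ci_low, ci_high - estimate)
  (hw / 1.96)^2
}

#' Hierarchical error model for mark-recapture survival estimates
#'
#' Survival estimates are modelled as normal around the latent survival
#' rate, with year-specific variance `V_t ~ Uniform(0, Vmax_t)` and
#' `Vmax_t ~ Gamma(shape, rate)`.  The gamma hyperparameters are fitted by
#' moment matching to the set of variances implied by the 95% CI half-widths
#' across years, so the stochastic variance ceiling represents the available
#' range of reported uncertainty.  When the implied variances have (near-)
#' zero spread the moment match degenerates and a fixed ceiling equal to the
#' common implied variance is used instead.
#'
#' @param survival data.frame with columns `year`, `age_class` (`"fledgling"`
#'   or `"older"`), `estimate`, `ci_low`, `ci_high`.
#' @return list of class `survival_error_model` with elements `shape`,
#'   `rate` (gamma hyperparameters, `NA` if degenerate), `fixed_vmax`
#'   (ceiling used when degenerate, else `NA`), `variances` (implied
#'   per-observation variances), and `degenerate` flag.
#' @export
survival_error_model <- function(survival) {
  need <- c("year", "age_class", "estimate", "ci_low", "ci_high")
  stopifnot(all(need %in% names(survival)))
  if (!all(survival$ci_low < survival$estimate &
             survival$estimate < survival$ci_high))
    stop_sspm("survival_error_model: need ci_low < estimate < ci_high")
  v <- ci_implied_variance(survival$estimate, survival$ci_low,
                           survival$ci_high)
  m <- mean(v)
  s2 <- stats::var(v)
  degenerate <- length(v) < 2 || !is.finite(s2) || s2 < 1e-12 * m^2
  if (degenerate) {
    out <- list(shape = NA_real_, rate = NA_real_, fixed_vmax = m,
                variances = v, degenerate = TRUE)
  } else {
    out <- list(shape = m^2 / s2, rate = m / s2, fixed_vmax = NA_real_,
                variances = v, degenerate = FALSE)
  }
  class(out) <- "survival_error_model"
  out
}

#' Simulate survival observations from the error model
#'
#' Generates mark-recapture-style survival estimates with 95% CIs from true
#' survival rates: per-observation variance ceilings are drawn from the
#' gamma distribution, variances uniformly below them, the estimate as a
#' normal deviate around truth, and the CI as estimate +/- 1.96 sd.
#' Estimates are clamped to (0.005, 0.995) to keep them valid proportions.
#'
#' @param truth data.frame with columns `year`, `age_class`, `phi` (true
#'   survival).
#' @param model a [survival_error_model()] (or list with `shape`, `rate`).
#' @param seed optional integer seed.
#' @return data.frame with columns `year, age_class, estimate, ci_low,
#'   ci_high`.
#' @export
simulate_survival_obs <- function(truth, model, seed = NULL) {
  with_seed(seed, {
    n <- nrow(truth)
    vmax <- if (isTRUE(model$degenerate)) rep(model$fixed_vmax, n)
            else stats::rgamma(n, model$shape, model$rate)
    V <- stats::runif(n, 0, vmax)
    est <- pmin(pmax(stats::rnorm(n, truth$phi, sqrt(V)), 0.005), 0.995)
    sdv <- sqrt(pmax(V, 1e-8))
    data.frame(year = truth$year, age_class = truth$age_class,
               estimate = est,
               ci_low = pmax(est - 1.96 * sdv, 1e-4),
               ci_high = pmin(est + 1.96 * sdv, 1 - 1e-4))
  })
}
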