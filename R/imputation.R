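# Imputation models for missing covariate segments.
#
# Two covariates have missing blocks in the emulated study design: female
# arrival mass (missing at the start of the series) is imputed as i.i.d.
# normal around the observed values, and the predation index (observed only
# in the later years) is imputed by a backward random walk anchored at the
# earliest observed year, so imputed values inherit serial autocorrelation
# and their uncertainty grows with distance from the data.

#' Imputation distribution for missing arrival-mass values
#'
#' Missing values are modelled as normal variates with mean and sd equal to
#' the sample moments of the observed values; draws happen within MCMC, but
#' the distribution itself is fixed by the observed data.
#'
#' @param x numeric series with `NA` for missing entries.
#' @return list of class `mass_imputation`: `mean`, `sd`, `missing` (index
#'   vector), and `draw(n)` returning a matrix of imputations
#'   (n draws x n missing).
#' @export
impute_arrival_mass <- function(x) {
  obs <- x[!is.na(x)]
  if (length(obs) < 2)
    stop_sspm("impute_arrival_mass: need >= 2 observed values")
  m <- mean(obs)
  s <- stats::sd(obs)
  miss <- which(is.na(x))
  structure(list(
    mean = m, sd = s, missing = miss,
    draw = function(n, seed = NULL) with_seed(seed,
      matrix(stats::rnorm(n * length(miss), m, s), n, length(miss)))
  ), class = "mass_imputation")
}

#' Backward random-walk imputation for the missing predation block
#'
#' The predation index is observed only from some year onward; the earlier
#' block is modelled as a backward random walk
#' `P[t-1] = P[t] + eps`, `eps ~ Normal(0, sigma_rw^2)`, anchored at the
#' earliest observed value.  The walk sd gets a weakly informative
#' half-normal prior whose scale is the sd of first differences of the
#' observed segment.
#'
#' @param observed numeric vector of observed values (contiguous block,
#'   chronological order), coming after the missing block.
#' @param n_missing number of missing years before the first observed year.
#' @return list of class `rw_imputation`: `anchor` (earliest observed
#'   value), `sigma_scale` (half-normal prior scale), `n_missing`, and
#'   `draw(n, sigma, seed)` returning a matrix (n x n_missing, chronological
#'   order) of imputed values for a given walk sd.
#' @export
impute_predation_random_walk <- function(observed, n_missing) {
  if (!length(observed))
    stop_sspm("impute_predation_random_walk: empty observed segment")
  stopifnot(n_missing >= 1)
  anchor <- observed[1]
  sigma_scale <- if (length(observed) >= 3) stats::sd(diff(observed)) else 1
  structure(list(
    anchor = anchor, sigma_scale = sigma_scale, n_missing = n_missing,
    draw = function(n, sigma, seed = NULL) with_seed(seed, {
      out <- matrix(NA_real_, n, n_missing)
      for (i in seq_len(n)) {
        steps <- stats::rnorm(n_missing, 0, sigma)
        # walk backwards from the anchor, then report chronologically
        out[i, ] <- rev(anchor + cumsum(steps))
      }
      out
    })
  ), class = "rw_imputation")
}

#' Posterior draws for a random-walk innovation sd
#'
#' Conjugate posterior for `sigma_rw` given an observed random-walk segment:
#' first differences are i.i.d. Normal(0, sigma_rw^2), so with a vague
#' inverse-gamma prior on the variance the posterior is
#' InvGamma(a0 + n/2, b0 + SS/2).  Used both to scale the prior inside the
#' full model and as a direct estimator in recovery checks.
#'
#' @param observed observed walk segment (chronological).
#' @param n_draws number of posterior draws.
#' @param a0,b0 inverse-gamma prior parameters (default vague, 0.001).
#' @param seed optional integer seed.
#' @return numeric vector of posterior draws of `sigma_rw`.
#' @export
rw_sigma_posterior <- function(observed, n_draws = 2000, a0 = 1e-3,
                               b0 = 1e-3, seed = NULL) {
  d <- diff(observed)
  if (length(d) < 2)
    stop_sspm("rw_sigma_posterior: need >= 3 observed values")
  with_seed(seed,
    sqrt(1 / stats::rgamma(n_draws, a0 + length(d) / 2,
                           b0 + sum(d^2) / 2)))
}
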