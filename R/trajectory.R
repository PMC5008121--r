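# Downstream trajectory analyses: broken-stick trend fit, no-data model
# validation, bootstrap covariate-sensitivity ranking, and period summaries.

#' One-breakpoint (broken-stick) trend fit of log counts
#'
#' Segmented regression of log counts on year with a single breakpoint,
#' found by profiling the residual sum of squares over candidate breakpoints
#' (all interior years plus a fine grid, with local refinement).  Slopes are
#' reported per segment on the log scale and as annual percentage rates of
#' change, `100 * (exp(slope) - 1)`.  The breakpoint standard error uses
#' the standard segmented-regression approximation (the gap-term SE divided
#' by the slope difference).  If the slope difference is not significant the
#' breakpoint is flagged unreliable rather than failing.
#'
#' @param years numeric vector of years.
#' @param counts positive counts (same length, >= 6).
#' @param equal_slopes constrain the two slopes to be equal (reduces to
#'   ordinary log-linear regression; no breakpoint is estimated).
#' @return object of class `broken_stick`: breakpoint (+SE), per-segment
#'   log-slopes and annual % rates (+SEs), `reliable` flag.
#' @export
fit_broken_stick <- function(years, counts, equal_slopes = FALSE) {
  stopifnot(length(years) == length(counts))
  if (length(years) < 6) stop_sspm("fit_broken_stick: need >= 6 years")
  if (any(counts <= 0)) stop_sspm("fit_broken_stick: counts must be > 0")
  o <- order(years)
  x <- as.numeric(years[o]); y <- log(counts[o]); n <- length(x)

  if (equal_slopes) {
    f <- stats::lm(y ~ x)
    sl <- stats::coef(f)[["x"]]; se <- summary(f)$coefficients["x", 2]
    out <- list(breakpoint = NA_real_, breakpoint_se = NA_real_,
                slopes = c(pre = sl, post = sl), slope_se = c(se, se),
                rates_pct = rep(100 * (exp(sl) - 1), 2),
                rates_pct_se = rep(100 * exp(sl) * se, 2),
                reliable = FALSE, equal_slopes = TRUE, fit = f)
    class(out) <- "broken_stick"
    return(out)
  }

  rss <- function(psi) {
    U <- pmax(x - psi, 0)
    sum(stats::lm.fit(cbind(1, x, U), y)$residuals^2)
  }
  lo <- x[3]; hi <- x[n - 2]   # >= 3 points per segment
  cand <- sort(unique(c(x[x >= lo & x <= hi], seq(lo, hi, length.out = 201))))
  rv <- vapply(cand, rss, 1)
  best <- which.min(rv)
  psi <- cand[best]; bestr <- rv[best]
  bl <- cand[max(1, best - 1)]; bh <- cand[min(length(cand), best + 1)]
  if (bh > bl) {
    op <- stats::optimize(rss, c(bl, bh))
    if (op$objective < bestr) { psi <- op$minimum; bestr <- op$objective }
  }

  U <- pmax(x - psi, 0)
  f <- stats::lm(y ~ x + U)
  cf <- stats::coef(f); vc <- stats::vcov(f)
  s1 <- cf[["x"]]; s2 <- cf[["x"]] + cf[["U"]]
  se1 <- sqrt(vc["x", "x"])
  se2 <- sqrt(vc["x", "x"] + vc["U", "U"] + 2 * vc["x", "U"])
  # breakpoint SE: gap-variable refit (Muggeo's approximation)
  Vv <- -as.numeric(x > psi)
  fg <- stats::lm(y ~ x + U + Vv)
  seg <- summary(fg)$coefficients
  psi_se <- if ("Vv" %in% rownames(seg) && abs(cf[["U"]]) > 1e-12)
    seg["Vv", 2] / abs(cf[["U"]]) else Inf
  pU <- summary(f)$coefficients
  p_diff <- if ("U" %in% rownames(pU)) pU["U", 4] else 1
  reliable <- is.finite(psi_se) && p_diff < 0.05

  out <- list(breakpoint = psi, breakpoint_se = psi_se,
              slopes = c(pre = s1, post = s2),
              slope_se = c(pre = se1, post = se2),
              rates_pct = 100 * (exp(c(s1, s2)) - 1),
              rates_pct_se = 100 * exp(c(s1, s2)) * c(se1, se2),
              reliable = reliable, equal_slopes = FALSE, rss = bestr,
              fit = f)
  class(out) <- "broken_stick"
  out
}

#' @export
print.broken_stick <- function(x, ...) {
  if (x$equal_slopes) {
    cat(sprintf("Log-linear trend: %.2f%% per year (SE %.2f)\n",
                x$rates_pct[1], x$rates_pct_se[1]))
    return(invisible(x))
  }
  cat(sprintf("Broken-stick trend fit%s\n",
              if (!x$reliable) " [breakpoint unreliable]" else ""))
  cat(sprintf("  breakpoint: %.2f (SE %.2f)\n", x$breakpoint,
              x$breakpoint_se))
  cat(sprintf("  pre-break:  %.2f%% per year (SE %.2f)\n", x$rates_pct[1],
              x$rates_pct_se[1]))
  cat(sprintf("  post-break: %.2f%% per year (SE %.2f)\n", x$rates_pct[2],
              x$rates_pct_se[2]))
  invisible(x)
}

# Shared forward-simulation machinery for posterior / marginal-posterior
# trajectory ensembles.
.simulate_ensemble <- function(fit, n_sim, seed = NULL, marginal = TRUE,
                               shuffle = FALSE, quiet = TRUE) {
  stopifnot(inherits(fit, "sspm"))
  M <- draws_matrix(fit$draws)
  T_ <- length(fit$data$years)
  nd <- nrow(M)

  # covariates: observed values plus posterior-mean point imputations
  cov <- as.data.frame(fit$data$covariates)
  for (vn in c("P", "A")) {
    miss <- which(is.na(cov[[vn]]))
    for (i in miss) {
      col <- paste0(vn, "[", i, "]")
      if (col %in% colnames(M)) cov[[vn]][i] <- mean(M[, col])
    }
  }
  if (anyNA(cov[c("P", "S0", "S1", "M0", "M1", "E2", "E3", "A", "D")]))
    stop_sspm("covariates incomplete after imputation point summaries")

  par_cols <- c("af0", "aa0", "a1", "a2", "a3", "b0",
                paste0("bb[", 1:10, "]"),
                paste0("Isel[", 1:3, "]"), paste0("Jsel[", 1:10, "]"),
                "N6[1]")
  # the validated model structure carries the influential covariates:
  # indicators are fixed at their posterior decision (inclusion > 0.5),
  # while continuous parameters are drawn from their marginals
  incl <- inclusion_probabilities(fit)
  I_fix <- as.numeric(incl[1:3] > 0.5)
  J_fix <- as.numeric(incl[4:13] > 0.5)
  with_seed(seed, {
    if (shuffle) cov <- cov[sample.int(T_), ]; cov$year <- fit$data$years
    N6s <- chs <- obs <- matrix(NA_real_, n_sim, T_)
    for (i in seq_len(n_sim)) {
      pick <- if (marginal)
        stats::setNames(vapply(par_cols, function(cc)
          M[sample.int(nd, 1), cc], 1), par_cols)
      else M[sample.int(nd, 1), par_cols]
      sc <- survival_coefficients(pick[["af0"]], pick[["aa0"]],
                                  pick[["a1"]], pick[["a2"]], pick[["a3"]],
        indicators = if (marginal) I_fix
                     else round(pick[paste0("Isel[", 1:3, "]")]))
      pc <- productivity_coefficients(pick[["b0"]],
        beta = pick[paste0("bb[", 1:10, "]")],
        indicators = if (marginal) J_fix
                     else round(pick[paste0("Jsel[", 1:10, "]")]))
      n6 <- max(1, round(pick[["N6[1]"]]))
      state <- c(pmax(round(fit$data$sprop * n6), 0), n6)
      for (t in seq_len(T_)) {
        sr <- survival_rates(sc, cov[t, ])
        Ct <- (state[6] - fit$data$c_center) / fit$data$c_scale
        bt <- productivity_rate(pc, cov[t, ], Ct)
        v <- vital_rates(min(max(sr["phi_f"], 1e-6), 1 - 1e-6),
                         min(max(sr["phi_a"], 1e-6), 1 - 1e-6),
                         min(max(bt, 1e-6), 1 - 1e-6))
        pr <- project_stochastic(state, v)
        N6s[i, t] <- state[6]; chs[i, t] <- pr$chicks
        state <- pr$state
      }
    }
    obs <- matrix(stats::rnorm(n_sim * T_, N6s, sqrt(fit$data$s2)),
                  n_sim, T_)
    ntrunc <- sum(obs < 0)
    if (ntrunc > 0 && !quiet)
      message("truncated ", ntrunc, " negative simulated counts at 0")
    obs[obs < 0] <- 0
    list(N6 = N6s, chicks = chs, pairs_obs = obs, years = fit$data$years)
  })
}

#' Validate the fitted model without the demographic data
#'
#' Re-simulates the population time series using only the covariates and
#' the marginal posterior distributions of the parameters: each parameter
#' is drawn independently from its own marginal posterior (deliberately
#' discarding the posterior covariance, which makes this a stringent test
#' of the descriptive power of the covariates), and the full stochastic
#' process is run forward from the initial state.  The check reports how
#' many observed counts fall inside the ensemble's 95% envelope.
#'
#' @param fit an [sspm()] fit.
#' @param n_sim ensemble size.
#' @param seed integer seed.
#' @param shuffle permute covariate years before simulating (negative
#'   control: destroys the covariate-trajectory association).
#' @return object of class `sspm_validation`: `envelope` (annual 2.5/50/
#'   97.5% quantiles of simulated observed counts), `coverage` (fraction of
#'   observed counts inside), `ensemble`.
#' @export
validate_without_data <- function(fit, n_sim = 1000, seed = NULL,
                                  shuffle = FALSE) {
  ens <- .simulate_ensemble(fit, n_sim = n_sim, seed = seed,
                            marginal = TRUE, shuffle = shuffle)
  qs <- apply(ens$pairs_obs, 2, stats::quantile,
              c(0.025, 0.25, 0.5, 0.75, 0.975))
  obs <- fit$data$counts$pairs
  inside <- obs >= qs[1, ] & obs <= qs[5, ]
  inside50 <- obs >= qs[2, ] & obs <= qs[4, ]
  structure(list(
    envelope = data.frame(year = ens$years, q2.5 = qs[1, ], q25 = qs[2, ],
                          median = qs[3, ], q75 = qs[4, ], q97.5 = qs[5, ],
                          observed = obs, inside = inside),
    coverage = mean(inside), coverage50 = mean(inside50),
    n_sim = n_sim, shuffle = shuffle,
    ensemble = ens), class = "sspm_validation")
}

#' @export
print.sspm_validation <- function(x, ...) {
  cat(sprintf(
    "No-data validation%s: %.0f%% of observed counts inside the 95%% envelope (%d simulations)\n",
    if (x$shuffle) " (shuffled covariates)" else "",
    100 * x$coverage, x$n_sim))
  invisible(x)
}

# posterior draws of the latent breeding-female trajectory, rows = draws
.n6_draws <- function(fit) {
  M <- draws_matrix(fit$draws)
  M[, paste0("N6[", seq_along(fit$data$years), "]"), drop = FALSE]
}

#' Bootstrap sensitivity of the trajectory to one covariate
#'
#' Compares the estimated breeding-female trajectories between a reference
#' fit and a fit with one covariate unavailable (its selection indicator
#' forced to 0).  Random pairs of posterior draws are selected from the two
#' fits and the mean squared residual between the two trajectories is
#' computed over the non-excluded years; higher values and greater
#' variability indicate that excluding the covariate reduces the model's
#' ability to recreate the population size.
#'
#' @param fit_with reference fit.
#' @param fit_without fit with the covariate excluded (same data, config).
#' @param n_boot number of bootstrap pairs.
#' @param exclude_years years dropped from the residual computation (e.g.
#'   years whose imputed covariate values may be overestimated).
#' @param seed integer seed.
#' @return object of class `covariate_sensitivity` with the bootstrap
#'   residual distribution and its summaries.
#' @export
covariate_sensitivity <- function(fit_with, fit_without, n_boot = 5000,
                                  exclude_years = NULL, seed = NULL) {
  if (!identical(fit_with$data$years, fit_without$data$years))
    stop_sspm("covariate_sensitivity: fits are on different year grids")
  keep <- !(fit_with$data$years %in% exclude_years)
  if (!any(keep)) stop_sspm("covariate_sensitivity: all years excluded")
  A <- .n6_draws(fit_with)[, keep, drop = FALSE]
  B <- .n6_draws(fit_without)[, keep, drop = FALSE]
  with_seed(seed, {
    i <- sample.int(nrow(A), n_boot, replace = TRUE)
    j <- sample.int(nrow(B), n_boot, replace = TRUE)
    res <- rowMeans((A[i, , drop = FALSE] - B[j, , drop = FALSE])^2)
    structure(list(residuals = res, median = stats::median(res),
                   q25 = unname(stats::quantile(res, 0.25)),
                   q75 = unname(stats::quantile(res, 0.75)),
                   n_boot = n_boot,
                   exclude_years = exclude_years),
              class = "covariate_sensitivity")
  })
}

#' @export
print.covariate_sensitivity <- function(x, ...) {
  cat(sprintf(
    "Covariate sensitivity: median MSR %.1f [IQR %.1f, %.1f] over %d bootstrap pairs\n",
    x$median, x$q25, x$q75, x$n_boot))
  invisible(x)
}

#' Rank covariates by their influence on the trajectory
#'
#' Runs [covariate_sensitivity()] of the reference fit against each
#' without-covariate fit and ranks covariates by the median of the
#' bootstrap residual distribution (rank 1 = most influential).
#'
#' @param fit_with reference fit.
#' @param fits_without named list of fits, each with one covariate excluded.
#' @param n_boot,exclude_years,seed passed to [covariate_sensitivity()].
#' @return data.frame with one row per covariate, ordered by rank, with the
#'   median and quartiles of the residual distribution.
#' @export
sensitivity_ranking <- function(fit_with, fits_without, n_boot = 5000,
                                exclude_years = NULL, seed = NULL) {
  stopifnot(length(names(fits_without)) == length(fits_without))
  seeds <- if (is.null(seed)) rep(list(NULL), length(fits_without))
           else as.list(seed + seq_along(fits_without))
  rows <- Map(function(f, s) {
    cs <- covariate_sensitivity(fit_with, f, n_boot = n_boot,
                                exclude_years = exclude_years, seed = s)
    data.frame(median = cs$median, q25 = cs$q25, q75 = cs$q75)
  }, fits_without, seeds)
  out <- do.call(rbind, rows)
  out <- data.frame(covariate = names(fits_without), out, row.names = NULL)
  out$rank <- rank(-out$median, ties.method = "first")
  out[order(out$rank), ]
}

#' Period summaries of vital rates
#'
#' Means and SDs of the annual (posterior-mean) vital rates before and
#' after a split year, plus two derived quantities: adult mortality
#' (1 - period-mean adult survival) and the proportion of a cohort
#' recruiting to the breeding population, computed as
#' `(b/2) * phi_f * phi_a^3` (female recruits at age 4 per breeding
#' female, using period-mean rates).
#'
#' @param x an `sspm` fit, or a data.frame with columns `year`, `phi_f`,
#'   `phi_a`, `b` of annual rates.
#' @param split_year first year of the later period.
#' @return data.frame with rows `early` / `late`.
#' @export
period_summaries <- function(x, split_year) {
  rates <- if (inherits(x, "sspm"))
    data.frame(year = x$data$years, phi_f = x$rates$phi_f$mean,
               phi_a = x$rates$phi_a$mean, b = x$rates$b$mean)
  else x
  stopifnot(all(c("year", "phi_f", "phi_a", "b") %in% names(rates)))
  early <- rates$year < split_year
  if (!any(early) || all(early))
    stop_sspm("period_summaries: split_year ", split_year,
              " leaves an empty period")
  one <- function(sel) {
    m <- colMeans(rates[sel, c("phi_f", "phi_a", "b")])
    s <- apply(rates[sel, c("phi_f", "phi_a", "b")], 2, stats::sd)
    data.frame(n_years = sum(sel),
               phi_f = m[["phi_f"]], phi_f_sd = s[["phi_f"]],
               phi_a = m[["phi_a"]], phi_a_sd = s[["phi_a"]],
               b = m[["b"]], b_sd = s[["b"]],
               adult_mortality = 1 - m[["phi_a"]],
               recruitment = (m[["b"]] / 2) * m[["phi_f"]] * m[["phi_a"]]^3)
  }
  out <- rbind(early = one(early), late = one(!early))
  out
}
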