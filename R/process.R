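# Demographic process: vital-rate link functions, transition matrix,
# deterministic and stochastic annual projection.
#
# The model tracks females only (1:1 sex ratio assumed), in six stage
# classes: stages 1-5 are pre-recruitment ages 1-5, stage 6 is breeding
# adults.  Stage-6 females produce female chicks at rate b/2 (one chick per
# pair, half female), chicks survive their first year at phi_f, and all
# older birds survive at phi_a.

#' Survival-function coefficients
#'
#' Coefficients of the logit-linear survival functions.  A shared predation
#' effect (`alpha_1`) acts on both age classes, an extra predation effect
#' (`alpha_2`) on fledglings only, and an SSTa lag-1 effect (`alpha_3`) on
#' both.  Each covariate effect is gated by a binary inclusion indicator.
#'
#' @param alpha_f0,alpha_a0 baseline logits for fledgling and older survival.
#' @param alpha_1 shared predation coefficient.
#' @param alpha_2 additional fledgling predation coefficient.
#' @param alpha_3 SSTa lag-1 coefficient.
#' @param indicators binary vector of length 3 gating
#'   (`alpha_1`, `alpha_2`, `alpha_3`).
#' @return object of class `survival_coefficients`.
#' @export
survival_coefficients <- function(alpha_f0, alpha_a0, alpha_1 = 0,
                                  alpha_2 = 0, alpha_3 = 0,
                                  indicators = c(1, 1, 1)) {
  stopifnot(length(indicators) == 3, all(indicators %in% c(0, 1)))
  structure(list(alpha_f0 = alpha_f0, alpha_a0 = alpha_a0,
                 alpha_1 = alpha_1, alpha_2 = alpha_2, alpha_3 = alpha_3,
                 indicators = stats::setNames(as.numeric(indicators), SURV_TERMS)),
            class = "survival_coefficients")
}

#' Productivity-function coefficients
#'
#' Coefficients of the logit-linear productivity function with ten covariate
#' terms in the canonical order `A, P, S0, S1, M0, M1, E2, E3, D, C`
#' (arrival mass, predation, SSTa lags 0/1, SAM lags 0/1, ENSO lags 2/3,
#' interspecific competition, intraspecific auto-covariate), each gated by a
#' binary inclusion indicator.
#'
#' @param beta_0 baseline logit.
#' @param beta numeric vector of length 10 (optionally named by term).
#' @param indicators binary vector of length 10.
#' @return object of class `productivity_coefficients`.
#' @export
productivity_coefficients <- function(beta_0, beta = numeric(10),
                                      indicators = rep(1, 10)) {
  stopifnot(length(beta) == 10, length(indicators) == 10,
            all(indicators %in% c(0, 1)))
  if (!is.null(names(beta)) && setequal(names(beta), PROD_TERMS))
    beta <- beta[PROD_TERMS]
  structure(list(beta_0 = beta_0,
                 beta = stats::setNames(as.numeric(beta), PROD_TERMS),
                 indicators = stats::setNames(as.numeric(indicators), PROD_TERMS)),
            class = "productivity_coefficients")
}

#' Annual vital rates
#'
#' @param phi_f fledgling survival probability in (0, 1).
#' @param phi_a older-age survival probability in (0, 1).
#' @param b productivity (chicks fledged per breeding pair) in (0, 1).
#' @return object of class `vital_rates`.
#' @export
vital_rates <- function(phi_f, phi_a, b) {
  v <- c(phi_f = phi_f, phi_a = phi_a, b = b)
  if (any(v <= 0 | v >= 1))
    stop_sspm("vital_rates: all rates must lie in the open unit interval")
  structure(as.list(v), class = "vital_rates")
}

.need_cov <- function(covrow, vars) {
  for (v in vars) {
    val <- covrow[[v]]
    if (is.null(val) || length(val) != 1 || is.na(val))
      stop_sspm("missing un-imputed covariate '", v, "'",
                if (!is.null(covrow$year)) paste0(" in year ", covrow$year))
  }
}

#' Annual survival rates from coefficients and covariates
#'
#' Evaluates the logit-linear survival functions: fledgling survival gets
#' the shared and extra predation effects plus the SSTa lag-1 effect; older
#' survival gets the shared predation and SSTa lag-1 effects.  Indicators
#' switch covariate effects off entirely, so an all-zero indicator vector
#' reproduces the covariate-free baselines.
#'
#' @param coeffs a [survival_coefficients()] object.
#' @param covrow one row of a [covariate_matrix()] (or any list with
#'   elements `P` and `S1`, optionally `year` for error messages).
#' @return named vector `c(phi_f, phi_a)`.
#' @export
survival_rates <- function(coeffs, covrow) {
  stopifnot(inherits(coeffs, "survival_coefficients"))
  I <- coeffs$indicators
  .need_cov(covrow, c(if (I[1] || I[2]) "P", if (I[3]) "S1"))
  P <- if (I[1] || I[2]) covrow$P else 0
  S1 <- if (I[3]) covrow$S1 else 0
  lf <- unname(coeffs$alpha_f0 +
    (I[[1]] * coeffs$alpha_1 + I[[2]] * coeffs$alpha_2) * P +
    I[[3]] * coeffs$alpha_3 * S1)
  la <- unname(coeffs$alpha_a0 + I[[1]] * coeffs$alpha_1 * P +
    I[[3]] * coeffs$alpha_3 * S1)
  c(phi_f = inv_logit(lf), phi_a = inv_logit(la))
}

#' Annual productivity from coefficients and covariates
#'
#' Evaluates the logit-linear productivity function over the ten covariate
#' terms.  The intraspecific auto-covariate `C` is supplied separately: it
#' is the current latent breeding-female count standardized with the fixed
#' observed-count mean and sd, so density dependence feeds back from the
#' process model.
#'
#' @param coeffs a [productivity_coefficients()] object.
#' @param covrow one row of a [covariate_matrix()].
#' @param C standardized breeding-female count for the year.
#' @return productivity `b` in (0, 1).
#' @export
productivity_rate <- function(coeffs, covrow, C) {
  stopifnot(inherits(coeffs, "productivity_coefficients"))
  J <- coeffs$indicators
  vals <- c(A = 0, P = 0, S0 = 0, S1 = 0, M0 = 0, M1 = 0, E2 = 0, E3 = 0,
            D = 0, C = 0)
  active <- PROD_TERMS[J == 1]
  .need_cov(c(covrow, list(C = C)), active)
  for (v in active) vals[v] <- if (v == "C") C else covrow[[v]]
  unname(inv_logit(coeffs$beta_0 + sum(J * coeffs$beta * vals)))
}

#' Deterministic stage-transition matrix
#'
#' Builds the 6x6 female-only projection matrix: fecundity
#' `phi_a * (b/2) * phi_f` into stage 1 from breeders, survival `phi_a` on
#' the subdiagonal for stage progression, and `phi_a` retention of breeding
#' adults.
#'
#' @param v a [vital_rates()] object.
#' @return 6x6 non-negative matrix.
#' @export
build_transition_matrix <- function(v) {
  stopifnot(inherits(v, "vital_rates"))
  R <- matrix(0, 6, 6)
  R[1, 6] <- v$phi_a * (v$b / 2) * v$phi_f
  for (s in 1:5) R[s + 1, s] <- v$phi_a
  R[6, 6] <- v$phi_a
  R
}

#' Expected next-year state
#'
#' Matrix-vector product of the transition matrix with the current state:
#' the expectation of the stochastic annual projection.
#'
#' @param state numeric vector of length 6 (females per stage).
#' @param v a [vital_rates()] object, or a pre-built 6x6 matrix.
#' @return real-valued expected state vector of length 6.
#' @export
project_deterministic <- function(state, v) {
  R <- if (is.matrix(v)) v else build_transition_matrix(v)
  if (length(state) != ncol(R))
    stop_sspm("project_deterministic: state has length ", length(state),
              ", expected ", ncol(R))
  as.numeric(R %*% state)
}

#' Stochastic annual projection with binomial demographic stochasticity
#'
#' Advances an integer stage-class state one year.  Stage-i females
#' (i = 1..5) survive to stage i + 1 as Binomial(n_i, phi_a); stage-6
#' survivors remain in stage 6 and are joined by stage-5 survivors.  Female
#' chicks are realized first as Binomial(n_6, b/2) (these are the chicks the
#' observation model sees), and next year's stage-1 entrants as
#' Binomial(chicks, phi_a * phi_f): the maternal phi_a factor of the
#' fecundity term is carried in the recruit-survival draw, so every
#' component's expectation equals the corresponding entry of
#' [project_deterministic()].
#'
#' @param state integer vector of length 6.
#' @param v a [vital_rates()] object.
#' @param seed optional integer seed for reproducibility.
#' @return list with `state` (integer vector of length 6 next year) and
#'   `chicks` (realized female chicks this year).
#' @export
project_stochastic <- function(state, v, seed = NULL) {
  stopifnot(inherits(v, "vital_rates"))
  if (length(state) != 6 || any(state < 0) || any(state != round(state)))
    stop_sspm("project_stochastic: state must be 6 non-negative integers")
  with_seed(seed, {
    chicks <- stats::rbinom(1, state[6], v$b / 2)
    nxt <- integer(6)
    nxt[1] <- stats::rbinom(1, chicks, v$phi_a * v$phi_f)
    for (s in 1:4) nxt[s + 1] <- stats::rbinom(1, state[s], v$phi_a)
    nxt[6] <- stats::rbinom(1, state[5], v$phi_a) +
      stats::rbinom(1, state[6], v$phi_a)
    list(state = nxt, chicks = chicks)
  })
}

#' Dominant eigenvalue of the transition matrix
#'
#' Asymptotic annual growth factor of the deterministic projection.
#'
#' @param v a [vital_rates()] object or 6x6 matrix.
#' @return largest real eigenvalue.
#' @export
growth_rate <- function(v) {
  R <- if (is.matrix(v)) v else build_transition_matrix(v)
  ev <- eigen(R, only.values = TRUE)$values
  max(Re(ev[abs(Im(ev)) < 1e-12]))
}

# Stable stage distribution (proportions relative to stage 6) of the
# deterministic matrix; used to initialize pre-recruitment stages.
stable_stage_proportions <- function(v) {
  R <- if (is.matrix(v)) v else build_transition_matrix(v)
  e <- eigen(R)
  i <- which.max(Re(e$values))
  w <- abs(Re(e$vectors[, i]))
  w / w[6]
}
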