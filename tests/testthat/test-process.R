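covrow0 <- list(year = 2000, P = 0, S0 = 0, S1 = 0, M0 = 0, M1 = 0,
                E2 = 0, E3 = 0, A = 0, D = 0)

test_that("survival link evaluates the logit functions", {
  sc <- survival_coefficients(alpha_f0 = -0.5, alpha_a0 = 2,
                              alpha_1 = -0.4, alpha_2 = -0.3, alpha_3 = 0.2)
  # zero covariates: baselines
  sr <- survival_rates(sc, covrow0)
  expect_equal(unname(sr), inv_logit(c(-0.5, 2)))

  # switched off: covariate values are irrelevant
  sc0 <- survival_coefficients(-0.5, 2, -0.4, -0.3, 0.2,
                               indicators = c(0, 0, 0))
  sr0 <- survival_rates(sc0, list(year = 1, P = 3, S1 = -2))
  expect_equal(unname(sr0), inv_logit(c(-0.5, 2)))

  # hand evaluation: alpha_f0=0, I1=I2=1, alpha_1=alpha_2=0.5, P=1
  sch <- survival_coefficients(0, 0, 0.5, 0.5, 0, indicators = c(1, 1, 0))
  expect_equal(unname(survival_rates(sch, list(P = 1, S1 = 0))[["phi_f"]]),
               1 / (1 + exp(-1)), tolerance = 1e-5)

  # missing un-imputed covariate names the covariate and year
  expect_error(survival_rates(sc, list(year = 1999, P = NA, S1 = 0)),
               "'P'.*1999")
})

test_that("productivity link evaluates the ten-term logit function", {
  pc <- productivity_coefficients(beta_0 = 0.3)
  expect_equal(productivity_rate(pc, covrow0, C = 0), inv_logit(0.3))

  # all indicators off: baseline regardless of covariates
  pcoff <- productivity_coefficients(0.3, beta = rep(2, 10),
                                     indicators = rep(0, 10))
  rowbig <- as.list(setNames(rep(5, 10), c("A","P","S0","S1","M0","M1",
                                           "E2","E3","D","C")))
  expect_equal(productivity_rate(pcoff, rowbig, C = 5), inv_logit(0.3))

  # negative density dependence: beta_0=0, only the auto-covariate active
  pcc <- productivity_coefficients(0, beta = c(rep(0, 9), -1),
                                   indicators = c(rep(0, 9), 1))
  expect_equal(productivity_rate(pcc, covrow0, C = 1), 0.26894, tolerance = 1e-5)
})

test_that("transition matrix has the stage-structured pattern", {
  R <- build_transition_matrix(vital_rates(1 - 1e-12, 1 - 1e-12, 1 - 1e-12))
  expect_equal(R[1, 6], 0.5, tolerance = 1e-9)
  expect_equal(diag(R[2:6, 1:5]), rep(1, 5), tolerance = 1e-9)
  expect_equal(R[6, 6], 1, tolerance = 1e-9)
  expect_equal(sum(R != 0), 7)

  R0 <- build_transition_matrix(vital_rates(0.5, 1e-12, 0.5))
  expect_true(all(R0 < 1e-11))
})

test_that("two independent eigen-solvers agree on the growth factor", {
  v <- vital_rates(0.37, 0.87, 0.51)
  R <- build_transition_matrix(v)
  # power iteration as the independent oracle
  x <- rep(1, 6)
  for (i in 1:2000) { x <- R %*% x; x <- x / sqrt(sum(x^2)) }
  lam_power <- sum(x * (R %*% x))
  expect_equal(growth_rate(v), lam_power, tolerance = 1e-10)
})

test_that("deterministic projection is the matrix-vector product", {
  v <- vital_rates(0.4, 0.9, 0.5)
  expect_equal(project_deterministic(rep(0, 6), v), rep(0, 6))

  nx <- project_deterministic(c(0, 0, 0, 0, 0, 100), v)
  expect_equal(nx[1], 0.9 * 0.25 * 0.4 * 100)  # 9.0
  expect_equal(nx[6], 90)

  # conservation: survival 1, no breeding, stages relabel but total is kept
  v1 <- vital_rates(0.5, 1 - 1e-14, 1e-14)
  st <- c(5, 4, 3, 2, 1, 100)
  for (k in 1:5) st <- project_deterministic(st, v1)
  expect_equal(sum(st), 115, tolerance = 1e-9)

  expect_error(project_deterministic(1:4, v), "length")
})

test_that("stochastic projection matches its deterministic expectation", {
  v <- vital_rates(0.4, 0.87, 0.5)
  z <- project_stochastic(rep(0L, 6), v, seed = 1)
  expect_equal(z$state, rep(0L, 6))
  expect_equal(z$chicks, 0)

  # forced structure at unit survival
  v1 <- vital_rates(1 - 1e-12, 1 - 1e-12, 1 - 1e-12)
  z1 <- project_stochastic(c(0L, 0L, 0L, 0L, 0L, 100L), v1, seed = 2)
  expect_equal(z1$state[6], 100)
  expect_equal(z1$state[1], z1$chicks)
  expect_true(z1$chicks >= 20 && z1$chicks <= 80)  # Binomial(100, 0.5)

  expect_error(project_stochastic(c(0.5, 0, 0, 0, 0, 10), v), "integer")

  # Monte Carlo mean vs deterministic expectation, 3-SE componentwise
  state <- c(10L, 10L, 10L, 10L, 10L, 200L)
  nrep <- 20000
  acc <- matrix(0, nrep, 6)
  set.seed(42)
  for (i in seq_len(nrep)) acc[i, ] <- project_stochastic(state, v)$state
  expected <- project_deterministic(state, v)
  se <- apply(acc, 2, sd) / sqrt(nrep)
  expect_true(all(abs(colMeans(acc) - expected) <= 3 * se + 1e-9))
})

test_that("survival is monotone in predation when the effect is negative", {
  sc <- survival_coefficients(-0.5, 2, alpha_1 = -0.4, indicators = c(1, 0, 0))
  set.seed(3)
  for (i in 1:50) {
    p <- sort(runif(2, -3, 3))
    lo <- survival_rates(sc, list(P = p[1], S1 = 0))[["phi_a"]]
    hi <- survival_rates(sc, list(P = p[2], S1 = 0))[["phi_a"]]
    expect_true(hi <= lo)
  }
})

test_that("repeated projection converges to the dominant eigenvalue", {
  v <- vital_rates(0.4, 0.9, 0.6)
  st <- c(1, 1, 1, 1, 1, 50)
  for (i in 1:500) {
    st_new <- project_deterministic(st, v)
    gf <- sum(st_new) / sum(st)
    st <- st_new / sum(st_new) * 100   # renormalize to avoid underflow
  }
  expect_equal(gf, growth_rate(v), tolerance = 1e-6)
})
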