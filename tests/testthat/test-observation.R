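test_that("count variance is the mean within-year variance over mean replicates", {
  one <- data.frame(year = 1, count = c(10, 10, 10))
  expect_equal(repeated_count_variance(one), 0)

  two <- data.frame(year = rep(1:2, each = 2),
                    count = c(0, 2, 0, sqrt(8)))  # variances 2 and 4
  expect_equal(repeated_count_variance(two), 1.5)

  # the study's reported ingredients on the raw count scale
  expect_equal(1727.3 / 4.7, 367.51, tolerance = 1e-2)

  none <- data.frame(year = 1:3, count = c(5, 6, 7))
  expect_error(repeated_count_variance(none), "supply")
})

test_that("count log-likelihood is a shift-invariant normal density", {
  # maximum at obs == latent
  expect_equal(count_loglik(100, 50, 100, 50, 25),
               2 * dnorm(0, 0, 5, log = TRUE))
  # closed form at z = 2
  expect_equal(count_loglik(100, 0, 110, 0, 25),
               dnorm(110, 100, 5, log = TRUE) + dnorm(0, 0, 5, log = TRUE))
  # strictly decreasing in |obs - latent|
  lls <- sapply(c(0, 5, 10, 20), function(d)
    count_loglik(100, 50, 100 + d, 50, 25))
  expect_true(all(diff(lls) < 0))
  # shifting latent and observed together leaves the density unchanged
  expect_equal(count_loglik(100, 50, 104, 47, 25),
               count_loglik(600, 550, 604, 547, 25))
  # additivity: a duplicated year doubles its contribution
  expect_equal(count_loglik(c(100, 100), c(50, 50), c(104, 104), c(47, 47), 25),
               2 * count_loglik(100, 50, 104, 47, 25))
  expect_error(count_loglik(1, 1, 1, 1, 0), "positive")
})

test_that("CI half-widths convert to implied variances", {
  v <- ci_implied_variance(0.87, 0.80, 0.94)
  expect_equal(sqrt(v), 0.0357, tolerance = 1e-3)
  expect_equal(v, 1.276e-3, tolerance = 1e-2)
  # asymmetric interval: conservative (larger) half-width
  expect_equal(ci_implied_variance(0.9, 0.7, 0.95), (0.2 / 1.96)^2)
  expect_error(ci_implied_variance(0.5, 0.6, 0.6), "degenerate CI")
})

test_that("survival error model moment-matches the CI-implied variances", {
  set.seed(8)
  n <- 40
  truth_v <- rgamma(n, 5, 3000)
  est <- runif(n, 0.3, 0.9)
  sv <- data.frame(year = 1:n, age_class = "older", estimate = est,
                   ci_low = est - 1.96 * sqrt(truth_v),
                   ci_high = est + 1.96 * sqrt(truth_v))
  em <- survival_error_model(sv)
  expect_false(em$degenerate)
  expect_equal(em$shape / em$rate, mean(truth_v), tolerance = 1e-9)
  expect_equal(em$shape / em$rate^2, var(truth_v), tolerance = 1e-9)

  # identical CIs: degenerate moment match falls back to a fixed ceiling
  svc <- data.frame(year = 1:5, age_class = "older", estimate = 0.85,
                    ci_low = 0.78, ci_high = 0.92)
  emc <- survival_error_model(svc)
  expect_true(emc$degenerate)
  expect_equal(emc$fixed_vmax, (0.07 / 1.96)^2)
})

test_that("simulated survival estimates are centred on truth", {
  em <- list(shape = 4, rate = 2000, degenerate = FALSE)
  tr <- data.frame(year = 1:400, age_class = "older", phi = 0.85)
  obs <- simulate_survival_obs(tr, em, seed = 9)
  se <- sd(obs$estimate) / sqrt(nrow(obs))
  expect_lt(abs(mean(obs$estimate) - 0.85), 3 * se)
  expect_true(all(obs$ci_low < obs$estimate & obs$estimate < obs$ci_high))
})
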