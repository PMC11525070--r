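test_that("the linear predictor at the standardized zero point is the intercept", {
  obs <- zero_observation(period = 1L)
  expect_equal(linear_predictor(obs, coef_only(mu_1 = 3.691)), 3.691)
  # previous growth of +1 mm/yr adds gamma_G,1
  obs$growth_prev <- 1
  expect_equal(linear_predictor(obs, coef_only(mu_1 = 3.691, G_1 = 0.575)),
               4.266)
  # all-zero coefficients give zero whatever the covariates
  obs$diameter_std <- 50; obs$local_ba_std <- -20
  expect_equal(linear_predictor(obs, coef_only(mu_1 = 0)), 0)
})

test_that("plot effects enter the predictor additively", {
  obs <- zero_observation(period = 2L)
  coef <- coef_only(mu_2 = 3.896, sigma_s = 1, eps = c(P1 = -0.5))
  expect_equal(linear_predictor(obs, coef), 3.396)
})

test_that("annual survival is the inverse logit and is monotone", {
  expect_equal(annual_survival(0), 0.5)
  expect_equal(annual_survival(3.691), 1 / (1 + exp(-3.691)),
               tolerance = 1e-12)
  expect_equal(annual_survival(3.691), 0.9756, tolerance = 1e-4)
  x <- seq(-4, 6, by = 0.5)
  expect_true(all(diff(annual_survival(x)) > 0))
  expect_error(annual_survival(Inf), "finite")
})

test_that("interval survival is the annual rate to the power delta-t", {
  expect_equal(interval_survival(0.7, 1), 0.7)
  expect_equal(interval_survival(0.9756, 6), 0.9756^6, tolerance = 1e-12)
  expect_equal(interval_survival(0.9756, 6), 0.8625, tolerance = 5e-4)
  s <- 0.98
  for (dt in 1:6) expect_lte(interval_survival(s, dt), s)
})

test_that("pointwise log-likelihood matches hand-computed values", {
  # survivor over 6 years at s = 0.9756: 6 * log(0.9756)
  eta <- qlogis(0.9756)
  obs <- zero_observation(period = 1L, delta_t = 6L, outcome = 1L)
  ll <- log_likelihood(obs, coef_only(mu_1 = eta))
  expect_equal(ll$pointwise, 6 * log(0.9756), tolerance = 1e-9)
  # death over the same interval: log(1 - 0.9756^6)
  obs$outcome <- 0L
  ll0 <- log_likelihood(obs, coef_only(mu_1 = eta))
  expect_equal(ll0$pointwise, log(1 - 0.9756^6), tolerance = 1e-12)
  expect_equal(ll0$pointwise, -1.984, tolerance = 3e-3)
  expect_equal(ll0$deviance, -2 * ll0$total)
})

test_that("for delta_t = 1 the term equals the Bernoulli log-likelihood", {
  set.seed(7)
  eta <- rnorm(50)
  out <- rbinom(50, 1, 0.5)
  term <- growsurv:::pointwise_loglik(eta, out, rep(1, 50))
  expect_equal(term, dbinom(out, 1, plogis(eta), log = TRUE),
               tolerance = 1e-12)
})

test_that("deviance is nonnegative for any Bernoulli data", {
  set.seed(8)
  for (i in 1:5) {
    n <- 30
    obs <- zero_observation(n = n, delta_t = sample(4:6, 1))
    obs$outcome <- rbinom(n, 1, 0.9)
    obs$growth_prev <- rnorm(n)
    dev <- log_likelihood(obs, coef_only(mu_1 = rnorm(1, 3, 1),
                                         G_1 = rnorm(1)))$deviance
    expect_gte(dev, 0)
  }
})

test_that("a perfectly-predicted survivor contributes zero log-likelihood", {
  obs <- zero_observation(outcome = 1L)
  ll <- log_likelihood(obs, coef_only(mu_1 = 40))  # s^dt -> 1
  expect_equal(ll$total, 0, tolerance = 1e-12)
})
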