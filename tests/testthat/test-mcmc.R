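test_that("MCMC matches the brute-force grid posterior on an intercept model", {
  set.seed(123)
  obs <- sim_intercept_obs(200, mu = 3.0)
  oracle <- grid_posterior(obs$outcome, obs$delta_t)
  fit <- fit_mcmc(obs, model_spec("base"),
                  mcmc = mcmc_config(chains = 3, iterations = 8000,
                                     burn_in = 2000, thin = 3),
                  seed = 31, include_random = FALSE)
  d <- as_draws_matrix(fit, "mu_1")
  expect_lt(abs(mean(d) - oracle$mean), 0.05)
  expect_lt(abs(sd(d) - oracle$sd) / oracle$sd, 0.10)
})

test_that("fixed seed gives identical draws; different seeds differ", {
  set.seed(42)
  obs <- sim_intercept_obs(100, mu = 2.5)
  mc <- mcmc_config(chains = 2, iterations = 1500, burn_in = 500, thin = 3)
  f1 <- suppressWarnings(fit_mcmc(obs, model_spec("base"), mcmc = mc,
                                  seed = 5, include_random = FALSE))
  f2 <- suppressWarnings(fit_mcmc(obs, model_spec("base"), mcmc = mc,
                                  seed = 5, include_random = FALSE))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$loglik, f2$loglik)
  f3 <- suppressWarnings(fit_mcmc(obs, model_spec("base"), mcmc = mc,
                                  seed = 6, include_random = FALSE))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("retained draw count equals chains x (iterations - burn-in) / thin", {
  set.seed(2)
  obs <- sim_intercept_obs(60, mu = 2)
  fit <- suppressWarnings(
    fit_mcmc(obs, model_spec("base"),
             mcmc = mcmc_config(chains = 2, iterations = 1300,
                                burn_in = 400, thin = 3),
             seed = 3, include_random = FALSE))
  expect_equal(dim(fit$draws)[1], (1300 - 400) %/% 3)
  expect_equal(dim(fit$draws)[2], 2L)
  expect_equal(nrow(fit$loglik), 2 * ((1300 - 400) %/% 3))
})

test_that("95% intervals for the intercept cover the truth across seeds", {
  # 20 small replicates; nominal coverage 0.95, accept >= 0.80
  mu_true <- 3.2
  hits <- 0L
  for (s in 1:20) {
    set.seed(400 + s)
    obs <- sim_intercept_obs(150, mu = mu_true)
    fit <- suppressWarnings(
      fit_mcmc(obs, model_spec("base"),
               mcmc = mcmc_config(chains = 2, iterations = 3000,
                                  burn_in = 1000, thin = 3),
               seed = 500 + s, include_random = FALSE))
    ci <- quantile(as_draws_matrix(fit, "mu_1"), c(0.025, 0.975))
    hits <- hits + (mu_true >= ci[1] && mu_true <= ci[2])
  }
  expect_gte(hits / 20, 0.80)
})

test_that("sampling a covariate whose truth is zero leaves others calibrated", {
  set.seed(77)
  n <- 400
  obs <- zero_observation(n = n, delta_t = 5L)
  obs$growth_prev <- rnorm(n, 1, 0.8)
  eta <- 3 + 0.6 * obs$growth_prev           # lagged-growth truth is 0
  obs$growth_lag <- rnorm(n, 1, 0.8)
  obs$outcome <- rbinom(n, 1, plogis(eta)^obs$delta_t)
  fit <- suppressWarnings(
    fit_mcmc(obs, model_spec(prev = TRUE, lag = TRUE),
             mcmc = mcmc_config(chains = 2, iterations = 6000,
                                burn_in = 2000, thin = 3),
             seed = 78, include_random = FALSE))
  d <- as_draws_matrix(fit, c("mu_1", "G_1", "G1_1"))
  ci_g <- quantile(d[, "G_1"], c(0.025, 0.975))
  ci_g1 <- quantile(d[, "G1_1"], c(0.025, 0.975))
  expect_true(ci_g[1] <= 0.6 && 0.6 <= ci_g[2])
  expect_true(ci_g1[1] <= 0 && 0 <= ci_g1[2])
})

test_that("the random-effects posterior agrees with an independent sampler", {
  # same hierarchical model expressed in JAGS: a cross-check of the plot
  # random-effect machinery on a small intercept + plot-effect dataset
  set.seed(300)
  n_plot <- 12L; per <- 25L
  eps <- rnorm(n_plot, 0, 0.8)
  obs <- zero_observation(n = n_plot * per, delta_t = 5L)
  obs$plot_id <- rep(sprintf("P%02d", 1:n_plot), each = per)
  eta <- 2.6 + eps[rep(1:n_plot, each = per)]
  obs$outcome <- rbinom(nrow(obs), 1, plogis(eta)^5)
  fit <- suppressWarnings(
    fit_mcmc(obs, model_spec("base"),
             mcmc = mcmc_config(chains = 2, iterations = 20000,
                                burn_in = 4000, thin = 10),
             seed = 301))
  d <- as_draws_matrix(fit, c("mu_1", "sigma_S"))

  mdl <- "model {
    for (i in 1:n) {
      logit(s[i]) <- mu + eps[plot[i]]
      a[i] ~ dbern(pow(s[i], 5))
    }
    mu ~ dnorm(0, 0.01)
    for (k in 1:K) { eps[k] ~ dnorm(0, tau) }
    sigma ~ dnorm(0, 0.25) T(0,)
    tau <- 1 / (sigma * sigma)
  }"
  jm <- rjags::jags.model(
    textConnection(mdl),
    data = list(n = nrow(obs), K = n_plot,
                plot = rep(1:n_plot, each = per), a = obs$outcome),
    n.chains = 2, n.adapt = 1000, quiet = TRUE,
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 302))
  update(jm, 2000, progress.bar = "none")
  sm <- rjags::coda.samples(jm, c("mu", "sigma"), n.iter = 10000, thin = 5,
                            progress.bar = "none")
  jmat <- do.call(rbind, lapply(sm, as.matrix))
  expect_lt(abs(mean(d[, "mu_1"]) - mean(jmat[, "mu"])), 0.2)
  expect_lt(abs(mean(d[, "sigma_S"]) - mean(jmat[, "sigma"])) /
              mean(jmat[, "sigma"]), 0.2)
})

test_that("prediction curves trim to the central 95% of observed growth", {
  ds <- simulate_forest(small_sim_config(), seed = 20)
  obs <- prepare_observations(ds$trees, ds$plots)
  fit <- suppressWarnings(
    fit_mcmc(obs, model_spec("selected"),
             mcmc = mcmc_config(chains = 2, iterations = 1500,
                                burn_in = 500, thin = 5),
             seed = 21))
  bounds <- quantile(obs$growth_prev[obs$period == 1], c(0.025, 0.975))
  expect_message(
    crv <- predict_survival_curve(fit, 1, 1000,
                                  growth = seq(-10, 20, by = 0.5)),
    "trimmed")
  expect_true(all(crv$growth >= bounds[1] & crv$growth <= bounds[2]))
  expect_true(all(crv$lower <= crv$mean & crv$mean <= crv$upper))
  expect_true(all(crv$mean > 0 & crv$mean < 1))
})

test_that("curves are nondecreasing when the draw-wise slope is positive", {
  set.seed(90)
  n <- 500
  obs <- zero_observation(n = n, delta_t = 5L)
  obs$growth_prev <- runif(n, 0, 3)
  obs$outcome <- rbinom(n, 1, plogis(2.5 + 0.8 * obs$growth_prev)^5)
  obs$elevation_std <- 0
  fit <- suppressWarnings(
    fit_mcmc(obs, model_spec(prev = TRUE),
             mcmc = mcmc_config(chains = 2, iterations = 4000,
                                burn_in = 1500, thin = 3),
             seed = 91, include_random = FALSE))
  d <- as_draws_matrix(fit, "G_1")
  crv <- predict_survival_curve(fit, 1, 1000)
  if (all(d > 0)) expect_true(all(diff(crv$mean) >= 0))
})
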