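# Independent oracles shared across test files.

# brute-force grid posterior for the intercept-only sub-model (1001-point
# grid over logit in [-2, 8], Normal(0, 10) prior)
grid_posterior <- function(outcome, delta_t, prior_sd = 10,
                           grid = seq(-2, 8, length.out = 1001)) {
  logpost <- vapply(grid, function(g) {
    s <- plogis(g)
    sum(ifelse(outcome == 1, delta_t * log(s), log(1 - s^delta_t))) +
      dnorm(g, 0, prior_sd, log = TRUE)
  }, numeric(1))
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  m <- sum(w * grid)
  list(mean = m, sd = sqrt(sum(w * (grid - m)^2)))
}

sim_intercept_obs <- function(n, mu, delta_t = 5L) {
  obs <- zero_observation(n = n, delta_t = delta_t)
  obs$outcome <- rbinom(n, 1, plogis(mu)^delta_t)
  obs
}
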