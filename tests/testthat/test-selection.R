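test_that("the candidate set has nine models with valid interaction structure", {
  cand <- build_candidate_set()
  expect_length(cand, 9L)
  # interactions always come with their main effect
  for (spec in cand) {
    if (spec$prev_x_ele) expect_true(spec$prev)
    if (spec$lag_x_ele) expect_true(spec$lag)
  }
  # the base model has no growth blocks; the full model has all four
  expect_equal(growsurv:::n_growth_blocks(cand$base), 0)
  expect_equal(growsurv:::n_growth_blocks(cand$full), 4)
  # all combinations are distinct
  keys <- vapply(cand, growsurv:::spec_label, character(1))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("an interaction without its main effect is rejected", {
  expect_error(model_spec(prev_x_ele = TRUE), "main effect")
  expect_error(model_spec(lag = FALSE, lag_x_ele = TRUE), "main effect")
})

test_that("the base design matrix has all non-growth covariates", {
  obs <- zero_observation(n = 2L)
  X <- build_design(obs, model_spec("base"))
  stubs <- unique(sub("_[123]$", "", colnames(X)))
  expect_setequal(stubs, c("mu", "y", "y2", "bas", "bas_x_ele",
                           "avP", "LI", "ele", "dist"))
  Xf <- build_design(obs, model_spec("full"))
  expect_setequal(setdiff(colnames(Xf), colnames(X)),
                  paste0(rep(c("G", "G_x_ele", "G1", "G1_x_ele"), each = 3),
                         "_", 1:3))
})

# a hand-built fit stub: 3 draws x 2 observations of pointwise log-likelihood
toy_fit <- function(ll) structure(list(loglik = ll), class = "posterior_fit")

test_that("deviance summaries match hand computation on a toy draw matrix", {
  ll <- matrix(c(-1, -2,
                 -1.5, -2.5,
                 -0.5, -3), nrow = 3, byrow = TRUE)
  dev <- deviance_posterior(toy_fit(ll))
  expect_equal(dev$draws, c(6, 8, 7))
  expect_equal(dev$mean, 7)
  expect_equal(dev$sd, 1)
})

test_that("WAIC on a 2-draw, 2-observation toy matches brute force", {
  ll <- matrix(c(-1.0, -2.0,
                 -1.4, -1.6), nrow = 2, byrow = TRUE)
  w <- compute_waic(toy_fit(ll))
  lppd <- log(mean(exp(ll[, 1]))) + log(mean(exp(ll[, 2])))
  p <- var(ll[, 1]) + var(ll[, 2])
  expect_equal(w$lppd, lppd, tolerance = 1e-12)
  expect_equal(w$p_waic, p, tolerance = 1e-12)
  expect_equal(w$waic, -2 * (lppd - p), tolerance = 1e-12)
  expect_gte(w$p_waic, 0)
})

test_that("a degenerate posterior has zero penalty and WAIC equal to deviance", {
  ll <- matrix(rep(c(-1.2, -0.7), each = 4), nrow = 4)
  w <- compute_waic(toy_fit(ll))
  expect_equal(w$p_waic, 0)
  expect_equal(w$waic, -2 * sum(ll[1, ]))
  expect_equal(w$waic, w$mean_deviance)
})

test_that("p_waic is nonnegative for random log-likelihood matrices", {
  set.seed(55)
  for (i in 1:10) {
    ll <- matrix(rnorm(60, -1, 0.5), nrow = 6)
    expect_gte(compute_waic(toy_fit(ll))$p_waic, 0)
  }
})

test_that("model ranking is ascending, zero-referenced and order-invariant", {
  mk <- function(waic) structure(list(waic = waic, p_waic = 1,
                                      lppd = 0, mean_deviance = waic - 2),
                                 class = "waic_result")
  res <- list(a = mk(105), b = mk(100), c = mk(112))
  tab <- rank_models(res)
  expect_equal(tab$model, c("b", "a", "c"))
  expect_equal(tab$delta_waic, c(0, 5, 12))
  tab2 <- rank_models(res[c(3, 1, 2)])
  expect_equal(tab2, tab)
  single <- rank_models(res["a"])
  expect_equal(single$delta_waic, 0)
})

test_that("exact WAIC ties break toward the model with fewer growth blocks", {
  mk <- function(waic) structure(list(waic = waic, p_waic = 1,
                                      lppd = 0, mean_deviance = waic),
                                 class = "waic_result")
  res <- list(full = mk(100), base = mk(100))
  specs <- list(full = model_spec("full"), base = model_spec("base"))
  tab <- rank_models(res, specs)
  expect_equal(tab$model[1], "base")
})
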