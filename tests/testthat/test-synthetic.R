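test_that("the default network has 216 plots on 85 transects of 1-8 plots", {
  set.seed(10)
  plots <- generate_plot_network(sim_config())
  expect_equal(nrow(plots), 216L)
  sizes <- table(plots$transect_id)
  expect_length(sizes, 85L)
  expect_true(all(sizes >= 1 & sizes <= 8))
  expect_true(all(plots$elevation_m >= 640 & plots$elevation_m <= 1417))
  expect_true(all(plots$soil_avP_ug_g > 0))
  expect_true(all(plots$epicentre_distance_km > 0))
})

test_that("a single plot with zero spread sits at the elevation midpoint", {
  set.seed(1)
  plots <- generate_plot_network(
    sim_config(n_plots = 1L, elevation_spread = 0, plot_elevation_sd = 0))
  expect_equal(plots$elevation_m, mean(c(640, 1417)))
})

test_that("more transects than plots is a config error", {
  expect_error(sim_config(n_plots = 10, n_transects = 20), "n_transects")
})

test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_forest(small_sim_config(), seed = 99)
  b <- simulate_forest(small_sim_config(), seed = 99)
  expect_identical(a$trees, b$trees)
  expect_identical(a$plots, b$plots)
  expect_identical(a$truth$eps, b$truth$eps)
  c <- simulate_forest(small_sim_config(), seed = 100)
  expect_false(identical(a$trees, c$trees))
})

test_that("an overwhelming intercept with no covariate effects kills no tree", {
  beta <- default_truth()$beta * 0
  beta[c("mu_1", "mu_2", "mu_3")] <- 20
  truth <- model_coefficients(beta, sigma_s = 0)
  ds <- simulate_forest(small_sim_config(truth = truth), seed = 12)
  expect_equal(sum(ds$trees$status == "dead"), 0L)
})

test_that("fast growers outlive slow growers pre-earthquake under the truth", {
  ds <- simulate_forest(sim_config(), seed = 13)
  obs <- prepare_observations(ds$trees, ds$plots)
  p1 <- obs[obs$period == 1L, ]
  for (cls in levels(growsurv:::elevation_class(1))) {
    ecls <- growsurv:::elevation_class(
      unstandardize(p1$elevation_std, covariate = "elevation"))
    fast <- p1$outcome[ecls == cls & p1$growth_prev > 2]
    slow <- p1$outcome[ecls == cls & p1$growth_prev < 0.5]
    if (length(fast) >= 500 && length(slow) >= 500)
      expect_gt(mean(fast), mean(slow))
  }
  # and in the pooled period-1 data, which is comfortably large
  expect_gt(mean(p1$outcome[p1$growth_prev > 2]),
            mean(p1$outcome[p1$growth_prev < 0.5]))
})

test_that("with no plot variance and flat covariates, plot survival is homogeneous", {
  beta <- default_truth()$beta * 0
  beta[c("mu_1", "mu_2", "mu_3")] <- 2.2
  truth <- model_coefficients(beta, sigma_s = 0)
  ds <- simulate_forest(small_sim_config(truth = truth), seed = 14)
  obs <- prepare_observations(ds$trees, ds$plots)
  deaths <- tapply(1 - obs$outcome, obs$plot_id, sum)
  totals <- tapply(obs$outcome, obs$plot_id, length)
  keep <- totals >= 10
  p <- suppressWarnings(
    chisq.test(cbind(deaths[keep], totals[keep] - deaths[keep])))$p.value
  expect_gt(p, 0.01)
})

test_that("measurement error of zero is the identity", {
  ds <- simulate_forest(small_sim_config(), seed = 15)
  out <- apply_measurement_error(ds, sd_mm = 0, gross_rate = 0)
  expect_identical(out$trees$diameter_mm, ds$trees$diameter_mm)
})

test_that("negative-growth frequency under noise matches the normal oracle", {
  # true growth 0.5 mm/yr over dt = 5, independent error sd 1 on both
  # endpoints: P(negative computed growth) = pnorm(-2.5 / sqrt(2))
  n <- 4000
  trees <- as_tree_table(data.frame(
    tree_id = sprintf("T%04d", rep(seq_len(n), each = 2)),
    plot_id = "P1", subplot = 6L,
    year = rep(c(1999L, 2004L), n),
    diameter_mm = rep(c(100, 102.5), n),
    status = "alive", stringsAsFactors = FALSE))
  ds <- structure(list(trees = trees), class = "synthetic_forest")
  set.seed(16)
  noisy <- apply_measurement_error(ds, sd_mm = 1)$trees
  wide <- matrix(noisy$diameter_mm, nrow = 2)
  frac_neg <- mean(wide[2, ] - wide[1, ] < 0)
  expected <- pnorm(-2.5 / sqrt(2))
  mc_sd <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(frac_neg - expected), 4 * mc_sd)
})

test_that("a 0.2% gross-error rate on ~4500 trees flags about nine trees", {
  ds <- simulate_forest(sim_config(), seed = 17)
  n_trees <- length(unique(ds$trees$tree_id))
  expect_gt(n_trees, 3000)
  set.seed(18)
  noisy <- apply_measurement_error(ds, sd_mm = 0, gross_rate = 0.002,
                                   gross_mm = 200)
  n_hit <- length(noisy$gross_error_ids)
  # Binomial(n_trees, 0.002): mean ~9, check within 4 sd
  expect_gt(n_hit, 0)
  expect_lt(abs(n_hit - n_trees * 0.002), 4 * sqrt(n_trees * 0.002) + 1)
  flagged <- clean_tree_table(noisy$trees)$flagged
  expect_true(all(noisy$gross_error_ids %in% flagged))
})

test_that("no tree record continues after simulated death", {
  ds <- simulate_forest(small_sim_config(), seed = 19)
  for (id in unique(ds$trees$tree_id[ds$trees$status == "dead"])) {
    rows <- ds$trees[ds$trees$tree_id == id, ]
    expect_equal(rows$status[nrow(rows)], "dead")
    expect_equal(sum(rows$status == "dead"), 1L)
  }
})
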