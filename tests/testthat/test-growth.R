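test_that("interval growth is the annualized diameter change", {
  expect_equal(interval_growth(100, 110, 5), 2)
  expect_equal(interval_growth(100, 100, 4), 0)
  # negative growth is returned, not dropped
  expect_equal(interval_growth(100, 95, 5), -1)
  expect_error(interval_growth(100, NA, 5), "imputation")
  expect_error(interval_growth(100, 110, 0), "delta_t")
})

test_that("the outlier rule is strict at 10 and -3 mm/yr", {
  rates <- data.frame(
    tree_id = c("a", "b", "c", "d", "e", "f"),
    rate = c(10.0, 12.3, -3.0, -3.5, -2.9, 10.01))
  expect_equal(flag_growth_outliers(rates), c("b", "d", "f"))
})

test_that("imputation anchors at the nearest measurement plus tercile growth", {
  # focal tree: 1983 = 100 mm, 1987 missing. Nine plot mates in three
  # diameter terciles; small tercile (like the focal tree) grows at
  # exactly 1.5 mm/yr over 1983-1987, so imputed = 100 + 1.5 * 4 = 106.
  mates <- do.call(rbind, lapply(1:9, function(i) {
    d0 <- c(90, 95, 98, 150, 160, 170, 250, 260, 270)[i]
    g <- c(1.5, 1.5, 1.5, 2.5, 2.5, 2.5, 3.5, 3.5, 3.5)[i]
    toy_tree_rows(sprintf("m%02d", i), c(1983, 1987), c(d0, d0 + g * 4))
  }))
  trees <- as_tree_table(rbind(
    toy_tree_rows("focal", c(1983, 1987), c(100, NA)), mates))
  expect_equal(
    impute_diameter(trees, "focal", 1987), 106)
})

test_that("a transposed-digit outlier is imputed near the plot prediction", {
  set.seed(9)
  mates <- do.call(rbind, lapply(1:12, function(i) {
    d0 <- runif(1, 80, 240)
    g <- rnorm(1, 1.5, 0.3)
    toy_tree_rows(sprintf("m%02d", i), c(1983, 1987, 1993),
                  c(d0, d0 + g * 4, d0 + g * 10))
  }))
  trees <- as_tree_table(rbind(
    toy_tree_rows("focal", c(1983, 1987, 1993), c(150, 510, 165)), mates))
  cl <- clean_tree_table(trees)
  expect_true("focal" %in% cl$flagged)
  fixed <- cl$trees$diameter_mm[cl$trees$tree_id == "focal" &
                                  cl$trees$year == 1987]
  expect_true(cl$trees$imputed[cl$trees$tree_id == "focal" &
                                 cl$trees$year == 1987])
  # within 3 x plot-tercile growth IQR of anchor + median-growth prediction
  rates <- (mates$diameter_mm[mates$year == 1987] -
              mates$diameter_mm[mates$year == 1983]) / 4
  pred <- 150 + median(rates) * 4
  expect_lt(abs(fixed - pred), 3 * max(IQR(rates), 1) + 1e-9)
})

test_that("a tree with no reliable measurement cannot be imputed and is excluded", {
  # the tree's only record has no usable diameter, so there is no anchor
  trees <- as_tree_table(rbind(
    toy_tree_rows("lonely", 1983, NA),
    toy_tree_rows("m1", c(1983, 1987), c(120, 126))))
  val <- impute_diameter(trees, "lonely", 1983)
  expect_true(is.na(val))
  expect_match(attr(val, "reason"), "anchor")
  cl <- clean_tree_table(trees)
  expect_true("lonely" %in% cl$exclusions$tree_id)
  expect_false("lonely" %in% cl$trees$tree_id)
})

test_that("cleaning leaves an already-clean table untouched", {
  ds <- simulate_forest(small_sim_config(), seed = 8)
  cl <- clean_tree_table(ds$trees)
  expect_equal(nrow(cl$imputations), 0L)
  expect_equal(cl$trees$diameter_mm, ds$trees$diameter_mm)
})
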