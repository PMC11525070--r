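test_that("the default schedule has five intervals in periods 1,1,2,3,3", {
  sch <- default_schedule()
  expect_equal(nrow(sch$intervals), 5L)
  expect_equal(sch$intervals$start_year, c(1983, 1987, 1993, 1999, 2004))
  expect_equal(sch$intervals$end_year, c(1987, 1993, 1999, 2004, 2009))
  expect_equal(sch$intervals$period, c(1L, 1L, 2L, 3L, 3L))
  expect_equal(sch$intervals$delta_t, c(4, 6, 6, 5, 5))
})

test_that("growth windows align: 1983-87 uses 1978-83 previous, 1974-78 lagged", {
  w <- growth_windows(default_schedule(), 1983)
  expect_equal(w$previous$start_year, 1978)
  expect_equal(w$previous$end_year, 1983)
  expect_equal(w$lagged$start_year, 1974)
  expect_equal(w$lagged$end_year, 1978)
})

test_that("window alignment holds for every assembled observation", {
  ds <- simulate_forest(small_sim_config(), seed = 4)
  obs <- prepare_observations(ds$trees, ds$plots)
  sch <- default_schedule()
  for (s in unique(obs$start_year)) {
    w <- growth_windows(sch, s)
    expect_equal(w$previous$end_year, s)
    expect_equal(w$lagged$end_year, w$previous$start_year)
  }
})

test_that("a tree first tagged in 1987 first contributes in 1999-2004", {
  trees <- as_tree_table(rbind(
    toy_tree_rows("late", c(1987, 1993, 1999, 2004, 2009),
                  c(100, 104, 108, 111, 114)),
    toy_tree_rows("old", c(1974, 1978, 1983, 1987, 1993, 1999, 2004, 2009),
                  c(100, 104, 108, 111, 114, 117, 119, 121),
                  subplot = 7L)))
  obs <- assemble_observations(trees, toy_plot_table())
  late <- obs[obs$tree_id == "late", ]
  expect_equal(min(late$start_year), 1999)
  old <- obs[obs$tree_id == "old", ]
  expect_equal(min(old$start_year), 1983)
  expect_equal(nrow(old), 5L)
})

test_that("trees outside the four central subplots yield no observations", {
  trees <- as_tree_table(
    toy_tree_rows("edge", c(1974, 1978, 1983, 1987),
                  c(100, 104, 108, 111), subplot = 1L))
  expect_error(assemble_observations(trees, toy_plot_table()),
               "no survival observations")
})

test_that("trees alive at start but unrecorded at end are excluded and logged", {
  trees <- as_tree_table(rbind(
    toy_tree_rows("lost", c(1974, 1978, 1983), c(100, 104, 108)),
    toy_tree_rows("kept", c(1974, 1978, 1983, 1987, 1993, 1999, 2004, 2009),
                  c(100, 104, 108, 111, 114, 117, 119, 121), subplot = 7L)))
  obs <- assemble_observations(trees, toy_plot_table())
  expect_false("lost" %in% obs$tree_id)
  excl <- attr(obs, "exclusions")
  expect_true("lost" %in% excl$tree_id)
  expect_match(excl$reason[excl$tree_id == "lost"][1], "unrecorded")
})

test_that("observation assembly is invariant to tree-table row order", {
  ds <- simulate_forest(small_sim_config(), seed = 6)
  obs1 <- prepare_observations(ds$trees, ds$plots)
  set.seed(1)
  shuffled <- ds$trees[sample(nrow(ds$trees)), ]
  class(shuffled) <- class(ds$trees)
  obs2 <- prepare_observations(shuffled, ds$plots)
  expect_equal(nrow(obs1), nrow(obs2))
  o2 <- obs2[order(obs2$tree_id, obs2$start_year), ]
  rownames(o2) <- NULL
  expect_equal(obs1$local_ba_std, o2$local_ba_std)
  expect_equal(obs1$outcome, o2$outcome)
})

test_that("a dying tree produces the outcome sequence 1, 1, 0", {
  trees <- as_tree_table(
    toy_tree_rows("doomed", c(1974, 1978, 1983, 1987, 1993, 1999),
                  c(100, 104, 108, 111, 114, NA),
                  c(rep("alive", 5), "dead")))
  obs <- assemble_observations(trees, toy_plot_table())
  expect_equal(obs$outcome, c(1L, 1L, 0L))
  expect_equal(obs$start_year, c(1983L, 1987L, 1993L))
})
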