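# Shared fixtures: tiny in-code datasets used across test files.

# a small but realistic synthetic study (fast to simulate and fit)
small_sim_config <- function(...) {
  sim_config(n_plots = 40, n_transects = 16, mean_stems_per_plot = 24, ...)
}

# long-form tree table built by hand: plot P1 at subplot 6 (central)
# unless stated otherwise
toy_tree_rows <- function(tree_id, years, diameters, status = NULL,
                          plot_id = "P1", subplot = 6L) {
  if (is.null(status)) status <- rep("alive", length(years))
  data.frame(tree_id = tree_id, plot_id = plot_id, subplot = subplot,
             year = years, diameter_mm = diameters, status = status,
             stringsAsFactors = FALSE)
}

as_tree_table <- function(df) {
  df$imputed <- FALSE
  df <- df[order(df$tree_id, df$year), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("tree_table", "data.frame")
  df
}

toy_plot_table <- function(plot_id = "P1", elevation_m = 1000,
                           soil = 14.88, landform = 20, dist = 18.17) {
  df <- data.frame(plot_id = plot_id, transect_id = "T01",
                   elevation_m = elevation_m, slope_deg = 20,
                   landform_index = landform, soil_avP_ug_g = soil,
                   epicentre_distance_km = dist, stringsAsFactors = FALSE)
  class(df) <- c("plot_table", "data.frame")
  df
}

# minimal observation rows with all covariates at standardized zero
zero_observation <- function(period = 1L, delta_t = 4L, outcome = 1L,
                             n = 1L) {
  df <- data.frame(
    tree_id = sprintf("T%d", seq_len(n)), plot_id = "P1", subplot = 6L,
    start_year = 1983L, end_year = 1983L + delta_t, delta_t = delta_t,
    period = period, outcome = outcome,
    diameter_std = 0, diameter_sq_std = 0, local_ba_std = 0,
    growth_prev = 0, growth_lag = 0, soil_p_std = 0, landform_std = 0,
    elevation_std = 0, distance_std = 0, stringsAsFactors = FALSE)
  class(df) <- c("survival_observations", "data.frame")
  df
}

# coefficients with only selected entries set
coef_only <- function(..., sigma_s = 0, eps = NULL) {
  vals <- c(...)
  model_coefficients(vals, sigma_s = sigma_s, eps = eps)
}

# the study-scale recovery fit (216 plots, default truth, default
# protocol), computed once and shared by the tests that need it
.study_cache <- new.env(parent = emptyenv())
study_recovery <- function() {
  if (!exists("fit", envir = .study_cache)) {
    ds <- simulate_forest(sim_config(), seed = 11)
    obs <- prepare_observations(ds$trees, ds$plots)
    fit <- suppressWarnings(
      fit_mcmc(obs, model_spec("selected"), mcmc = mcmc_config(),
               seed = 1011))
    assign("ds", ds, envir = .study_cache)
    assign("obs", obs, envir = .study_cache)
    assign("fit", fit, envir = .study_cache)
  }
  list(ds = get("ds", envir = .study_cache),
       obs = get("obs", envir = .study_cache),
       fit = get("fit", envir = .study_cache))
}
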