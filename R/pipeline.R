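#' Write a tree or plot table to CSV
#'
#' @param x A `tree_table` or `plot_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  df <- as.data.frame(x)
  if ("imputed" %in% names(df)) df$imputed <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full growth-survival pipeline
#'
#' Orchestrates simulate (optional) -> prepare -> fit -> select (optional)
#' -> report, writing every artefact plus a run manifest into `out_dir`.
#' Any stage failure halts with an error naming the stage; artefacts
#' already written are retained.
#'
#' @param config A list (or path to a YAML file, parsed with the `yaml`
#'   package) with elements:
#'   \describe{
#'     \item{seed}{master seed; every stochastic stage derives from it}
#'     \item{data}{either `list(synthetic = <sim_config overrides>)` or
#'       `list(trees = "trees.csv", plots = "plots.csv")`}
#'     \item{model}{`"selected"` (default), `"base"`, `"full"`, or a list
#'       of flags for [model_spec()]}
#'     \item{mcmc}{arguments for [mcmc_config()]}
#'     \item{run_selection}{fit and rank the nine candidate models
#'       (default `FALSE`; expensive)}
#'     \item{curve_elevations}{elevations (m) for the growth-survival curve
#'       export, default `c(800, 1000, 1200)`}
#'   }
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- list(seed = seed,
                   package_version = as.character(utils::packageVersion("growsurv")),
                   config_hash = config_hash(config),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  schedule <- default_schedule()

  # --- simulate or load -----------------------------------------------
  if (!is.null(config$data$synthetic)) {
    sim_args <- config$data$synthetic
    sim_args <- sim_args[names(sim_args) != ""]
    cfg <- stage("simulate", do.call(sim_config, sim_args))
    ds <- stage("simulate", simulate_forest(cfg, seed = seed))
    trees <- ds$trees; plots <- ds$plots
    write_table_csv(trees, file.path(out_dir, "trees.csv"))
    write_table_csv(plots, file.path(out_dir, "plots.csv"))
    jsonlite::write_json(
      list(beta = as.list(ds$truth$beta), sigma_s = ds$truth$sigma_s),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    manifest$data <- "synthetic"
  } else {
    trees <- stage("prepare", read_tree_table(config$data$trees, schedule))
    plots <- stage("prepare", read_plot_table(config$data$plots))
    manifest$data <- "csv"
  }

  # --- prepare --------------------------------------------------------
  obs <- stage("prepare", prepare_observations(trees, plots, schedule))
  write_observations(obs, file.path(out_dir, "observations.csv"))
  cleaning <- attr(obs, "cleaning")
  log_df <- rbind(
    if (nrow(cleaning$exclusions))
      data.frame(what = "tree excluded", id = cleaning$exclusions$tree_id,
                 detail = cleaning$exclusions$reason),
    if (length(cleaning$flagged))
      data.frame(what = "growth outlier flagged", id = cleaning$flagged,
                 detail = "window growth outside (-3, 10) mm/yr"),
    if (nrow(attr(obs, "exclusions")))
      data.frame(what = "observation excluded",
                 id = attr(obs, "exclusions")$tree_id,
                 detail = attr(obs, "exclusions")$reason))
  if (is.null(log_df))
    log_df <- data.frame(what = character(), id = character(),
                         detail = character())
  utils::write.csv(log_df, file.path(out_dir, "log.csv"), row.names = FALSE)

  # --- fit ------------------------------------------------------------
  spec <- if (is.list(config$model)) do.call(model_spec, config$model)
          else model_spec(if (is.null(config$model)) "selected" else config$model)
  mcmc <- do.call(mcmc_config, if (is.null(config$mcmc)) list() else config$mcmc)
  fit <- stage("fit", fit_mcmc(obs, spec, mcmc = mcmc, seed = seed + 1L))
  saveRDS(fit, file.path(out_dir, "fit.rds"))

  # --- select ---------------------------------------------------------
  if (isTRUE(config$run_selection)) {
    ranking <- stage("select",
                     select_models(obs, mcmc = mcmc, seed = seed + 100L))
    utils::write.csv(ranking, file.path(out_dir, "ranking.csv"),
                     row.names = FALSE)
    manifest$best_model <- ranking$model[1L]
  }

  # --- report ---------------------------------------------------------
  summ <- stage("report", summarize_posterior(fit))
  utils::write.csv(summ, file.path(out_dir, "summary.csv"), row.names = FALSE)
  eles <- if (is.null(config$curve_elevations)) c(800, 1000, 1200)
          else config$curve_elevations
  # period x elevation-class combinations without observations are skipped
  curves <- stage("report", do.call(rbind, lapply(1:3, function(q)
    do.call(rbind, lapply(eles, function(e)
      tryCatch(predict_survival_curve(fit, q, e),
               error = function(err) NULL))))))
  utils::write.csv(curves, file.path(out_dir, "curves.csv"),
                   row.names = FALSE)
  series <- stage("report", basal_area_series(trees, plots, schedule))
  utils::write.csv(series, file.path(out_dir, "series.csv"),
                   row.names = FALSE)

  manifest$n_observations <- nrow(obs)
  manifest$n_survival_intervals <- nrow(schedule$intervals)
  manifest$n_periods <- length(unique(schedule$intervals$period))
  manifest$n_plots <- nrow(plots)
  manifest$model <- spec_label(spec)
  manifest$mcmc <- unclass(mcmc)
  manifest$max_rhat <- max(fit$diagnostics$rhat, na.rm = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}
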