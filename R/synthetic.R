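#' Configuration for the synthetic forest simulator
#'
#' The simulator emulates the structure of a permanent-plot network in a
#' monodominant montane beech forest: 216 plots of 0.04 ha on 85 transects
#' of 1-8 plots, 16 subplots per plot, trees tagged at >= 30 mm diameter,
#' eight measurements between 1974 and 2009, elevations spanning
#' 640-1417 m, growth declining with elevation and neighbourhood basal
#' area, survival drawn from the package's own interval-survival model with
#' a reference coefficient set as truth (see [default_truth()]), and an
#' earthquake between the 1993 and 1999 measurements.
#'
#' The earthquake enters in two ways. The survival truth already carries
#' the disturbance in its period-2 regime (distance-from-epicentre effect),
#' so simulated outcomes stay draws from the model likelihood; the
#' `eq_extra_mortality` knob adds non-model excess mortality and defaults
#' to 0. Independently, a distance-dependent fraction of survivors is
#' injured and grows more slowly from 1993 onwards
#' (`injury_growth_factor`), which reshapes the post-earthquake growth
#' distribution without touching the survival likelihood.
#'
#' @param n_plots,n_transects,max_plots_per_transect Network layout.
#' @param elevation_range Metres; `elevation_spread` in \[0, 1\] scales how
#'   widely transect mean elevations span the range (0 puts every transect
#'   at the midpoint), `plot_elevation_sd` jitters plots within a transect.
#' @param landform_mean,landform_sd,slope_mean,slope_sd,log_soil_p_mean,log_soil_p_sd,log_distance_mean,log_distance_sd
#'   Plot covariate distributions, centred near the standardization zero
#'   points.
#' @param years Measurement years (default eight, 1974-2009).
#' @param mean_stems_per_plot Initial expected tagged stems per plot
#'   (default 20, sized so the default network yields roughly 4,500
#'   central-subplot tree-interval observations).
#' @param stem_density_sd Between-plot lognormal sd of initial stocking
#'   (log scale). Plot networks have large exogenous density variation
#'   (site history, stocking); this also keeps the neighbourhood
#'   basal-area covariate from being dominated by mortality feedback,
#'   which would make it endogenous to the plot random effect.
#' @param diameter_shape,diameter_scale Initial diameters are
#'   `30 + rgamma(shape, scale)` mm.
#' @param growth_intercept Log of mean annual growth (mm/yr) at the
#'   standardized zero point; `growth_elev`, `growth_bas`, `growth_diam`
#'   are log-linear slopes on standardized elevation (per 100 m), basal
#'   area (per m2/ha) and diameter (per mm); `growth_sd` is the Gaussian
#'   noise sd of the realised rate (mm/yr).
#' @param growth_tree_sd Lognormal sd (log scale) of a persistent
#'   tree-level growth multiplier: trees differ durably in vigour
#'   (microsite, suppression history), which widens the growth
#'   distribution and makes consecutive windows autocorrelated — both
#'   features of real remeasurement data that the survival model's two
#'   growth covariates rely on.
#' @param truth A [model_coefficients()] object used as survival truth.
#' @param recruit_rate Expected recruits per plot per year, appearing at
#'   30 mm.
#' @param eq_year_start,eq_year_end The measurement interval containing the
#'   earthquake.
#' @param injury_intercept,injury_dist_slope Injury probability is
#'   `plogis(injury_intercept - injury_dist_slope * dist_std)`.
#' @param injury_growth_factor Growth multiplier for injured trees from the
#'   earthquake interval onwards.
#' @param eq_extra_mortality Extra interval death probability at the
#'   distance zero point (decays as `exp(-dist_std)`); default 0.
#' @param seed Optional default seed used by [simulate_forest()].
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_plots = 216L, n_transects = 85L,
                       max_plots_per_transect = 8L,
                       elevation_range = c(640, 1417),
                       elevation_spread = 1, plot_elevation_sd = 30,
                       landform_mean = 20, landform_sd = 8,
                       slope_mean = 25, slope_sd = 8,
                       log_soil_p_mean = 2.7, log_soil_p_sd = 0.5,
                       log_distance_mean = 2.9, log_distance_sd = 0.45,
                       years = default_years(),
                       mean_stems_per_plot = 20, stem_density_sd = 0.45,
                       diameter_shape = 1.8, diameter_scale = 75,
                       growth_intercept = 0.1, growth_elev = -0.25,
                       growth_bas = -0.006, growth_diam = -0.0005,
                       growth_sd = 0.4, growth_tree_sd = 0.4,
                       truth = default_truth(),
                       recruit_rate = 0.15,
                       eq_year_start = 1993L, eq_year_end = 1999L,
                       injury_intercept = -2.2, injury_dist_slope = 1,
                       injury_growth_factor = 0.6,
                       eq_extra_mortality = 0,
                       seed = NULL) {
  if (n_plots < 1L) stop("n_plots must be >= 1")
  if (n_plots > 1L && n_plots < n_transects)
    stop("n_plots must be at least n_transects")
  sds <- c(plot_elevation_sd, landform_sd, slope_sd, log_soil_p_sd,
           log_distance_sd, growth_sd)
  if (any(sds < 0)) stop("spread parameters must be >= 0")
  if (eq_extra_mortality < 0 || eq_extra_mortality > 1)
    stop("eq_extra_mortality must be in [0, 1]")
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic plot network
#'
#' Assigns plots to transects (every transect gets at least one plot, none
#' more than the configured maximum), draws transect mean elevations across
#' the configured range with plot-level jitter, and draws the remaining
#' plot covariates from distributions centred near the standardization zero
#' points. Plots on the same transect share a base epicentre distance.
#'
#' @param config A [sim_config()].
#' @return A `plot_table` data frame.
#' @export
generate_plot_network <- function(config) {
  n <- config$n_plots
  nt <- if (n == 1L) 1L else config$n_transects
  sizes <- rep(1L, nt)
  extra <- n - nt
  while (extra > 0L) {
    open <- which(sizes < config$max_plots_per_transect)
    pick <- open[sample.int(length(open), 1L)]
    sizes[pick] <- sizes[pick] + 1L
    extra <- extra - 1L
  }
  rng <- config$elevation_range
  mid <- mean(rng)
  t_ele <- mid + config$elevation_spread * (stats::runif(nt) - 0.5) *
    diff(rng)
  t_dist <- exp(stats::rnorm(nt, config$log_distance_mean,
                             config$log_distance_sd))
  transect <- rep(seq_len(nt), sizes)
  ele <- pmin(pmax(t_ele[transect] +
                     stats::rnorm(n, 0, config$plot_elevation_sd),
                   rng[1]), rng[2])
  df <- data.frame(
    plot_id = sprintf("P%03d", seq_len(n)),
    transect_id = sprintf("T%02d", transect),
    elevation_m = ele,
    slope_deg = pmin(pmax(stats::rnorm(n, config$slope_mean,
                                       config$slope_sd), 0), 60),
    landform_index = pmin(pmax(stats::rnorm(n, config$landform_mean,
                                            config$landform_sd), 0.5), 45),
    soil_avP_ug_g = exp(stats::rnorm(n, config$log_soil_p_mean,
                                     config$log_soil_p_sd)),
    epicentre_distance_km = pmin(pmax(
      t_dist[transect] * exp(stats::rnorm(n, 0, 0.05)), 2), 80),
    stringsAsFactors = FALSE
  )
  class(df) <- c("plot_table", "data.frame")
  df
}

#' Simulate a tagged-tree remeasurement dataset
#'
#' Forward simulation over the measurement schedule: each living tree's
#' diameter increments by an annual growth draw (log-linear in standardized
#' elevation, neighbourhood basal area and diameter, Gaussian noise), and
#' survival to the next measurement is a Bernoulli draw with probability
#' `S^dt`, where `S` comes from [linear_predictor()] at the tree's current
#' covariates, the interval's period regime and the plot's random effect —
#' the exact likelihood the fitting module implements. Growth covariates
#' for intervals that precede the tree's second window are taken as zero
#' (the standardized centre); such tree-intervals are exactly the ones
#' [assemble_observations()] later excludes. Recruits appear at 30 mm with
#' the configured rate. Injury and optional extra mortality follow the
#' earthquake settings in the config.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (falls back to `config$seed`); fixed seed gives
#'   byte-identical output.
#' @return Object of class `synthetic_forest`: list with `trees` (a
#'   `tree_table` of *true* diameters), `plots`, `truth` (the coefficient
#'   set including the realised plot effects), `injured` (tree ids) and
#'   `config`.
#' @export
simulate_forest <- function(config = sim_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  plots <- generate_plot_network(config)
  n_plots <- nrow(plots)
  yrs <- config$years
  K <- length(yrs)
  std <- standardization_config()

  eps <- stats::rnorm(n_plots, 0, config$truth$sigma_s)
  names(eps) <- plots$plot_id
  truth <- model_coefficients(config$truth$beta, config$truth$sigma_s, eps)

  ele_std <- standardize(plots$elevation_m, std, "elevation")
  dist_std <- standardize(plots$epicentre_distance_km, std, "distance")

  # state vectors, grown as recruits appear; stocking varies between
  # plots beyond Poisson noise
  dens <- config$mean_stems_per_plot *
    exp(stats::rnorm(n_plots, 0, config$stem_density_sd) -
          config$stem_density_sd^2 / 2)
  n0 <- stats::rpois(n_plots, dens)
  if (config$n_plots == 1L && config$mean_stems_per_plot >= 1)
    n0 <- max(n0, 1L)
  plot_ix <- rep(seq_len(n_plots), n0)
  n_tree <- length(plot_ix)
  subplot <- sample.int(16L, n_tree, replace = TRUE)
  dmat <- matrix(NA_real_, n_tree, K)
  dmat[, 1L] <- 30 + stats::rgamma(n_tree, config$diameter_shape,
                                   scale = config$diameter_scale)
  alive_from <- rep(1L, n_tree)   # first measurement index
  dead_at <- rep(NA_integer_, n_tree)  # measurement index of death record
  injured <- rep(FALSE, n_tree)
  vigour <- exp(stats::rnorm(n_tree, 0, config$growth_tree_sd) -
                  config$growth_tree_sd^2 / 2)
  internal <- vector("list", K - 1L)  # per-interval covariates, for audits

  period_of <- function(start_year) {
    iv <- default_period_lookup(config, start_year)
    iv
  }
  # the first two measurement intervals only supply growth windows; the
  # first survival interval starts at the third measurement
  first_obs_year <- yrs[min(3L, K)]

  for (k in seq_len(K - 1L)) {
    dt <- yrs[k + 1L] - yrs[k]
    live <- which(!is.na(dmat[, k]) & is.na(dead_at))
    if (length(live) == 0L) next
    ba <- block_basal_area(plot_ix[live], subplot[live], dmat[live, k],
                           n_plots)
    # injury is assigned at the start of the earthquake interval
    if (yrs[k] == config$eq_year_start) {
      p_inj <- stats::plogis(config$injury_intercept -
                               config$injury_dist_slope *
                               dist_std[plot_ix[live]])
      injured[live] <- stats::runif(length(live)) < p_inj
    }
    mu_g <- vigour[live] *
      exp(config$growth_intercept +
            config$growth_elev * ele_std[plot_ix[live]] +
            config$growth_bas * (ba - 50) +
            config$growth_diam * (dmat[live, k] - 164))
    if (config$injury_growth_factor != 1)
      mu_g <- mu_g * ifelse(injured[live] & yrs[k] >= config$eq_year_start,
                            config$injury_growth_factor, 1)
    g <- stats::rnorm(length(live), mu_g, config$growth_sd)
    d_next <- pmax(dmat[live, k] + g * dt, 5)

    g_prev <- if (k >= 2L) {
      gp <- (dmat[live, k] - dmat[live, k - 1L]) / (yrs[k] - yrs[k - 1L])
      ifelse(is.na(gp), 0, gp)
    } else rep(0, length(live))
    g_lag <- if (k >= 3L) {
      gl <- (dmat[live, k - 1L] - dmat[live, k - 2L]) /
        (yrs[k - 1L] - yrs[k - 2L])
      ifelse(is.na(gl), 0, gl)
    } else rep(0, length(live))

    obs <- data.frame(
      tree_id = sprintf("S%05d", live), plot_id = plots$plot_id[plot_ix[live]],
      subplot = subplot[live], start_year = yrs[k], end_year = yrs[k + 1L],
      delta_t = dt, period = period_of(yrs[k]), outcome = 1L,
      diameter_std = dmat[live, k] - 164,
      diameter_sq_std = (dmat[live, k] - 164)^2,
      local_ba_std = ba - 50,
      growth_prev = g_prev, growth_lag = g_lag,
      soil_p_std = standardize(plots$soil_avP_ug_g[plot_ix[live]], std,
                               "soil_p"),
      landform_std = standardize(plots$landform_index[plot_ix[live]], std,
                                 "landform"),
      elevation_std = ele_std[plot_ix[live]],
      distance_std = dist_std[plot_ix[live]],
      stringsAsFactors = FALSE)
    class(obs) <- c("survival_observations", "data.frame")
    # pre-study intervals (before the first survival interval) are
    # simulated without the plot effect, so that the stand state entering
    # the study period is exogenous to the random effects the model
    # estimates; from the first survival interval onwards every outcome is
    # a draw from the model's own likelihood
    use_truth <- if (yrs[k] < first_obs_year)
      model_coefficients(truth$beta, truth$sigma_s) else truth
    s_annual <- stats::plogis(linear_predictor(obs, use_truth))
    p_live <- s_annual^dt
    if (config$eq_extra_mortality > 0 &&
        yrs[k] >= config$eq_year_start && yrs[k] < config$eq_year_end) {
      p_extra <- pmin(config$eq_extra_mortality *
                        exp(-dist_std[plot_ix[live]]), 1)
      p_live <- p_live * (1 - p_extra)
    }
    surv <- stats::runif(length(live)) < p_live
    dmat[live[surv], k + 1L] <- d_next[surv]
    dead_at[live[!surv]] <- k + 1L
    obs$outcome <- as.integer(surv)
    internal[[k]] <- obs

    n_new <- stats::rpois(n_plots, config$recruit_rate * dt)
    if (sum(n_new) > 0L) {
      np <- sum(n_new)
      plot_ix <- c(plot_ix, rep(seq_len(n_plots), n_new))
      subplot <- c(subplot, sample.int(16L, np, replace = TRUE))
      add <- matrix(NA_real_, np, K)
      add[, k + 1L] <- 30 + stats::rexp(np, rate = 1 / 5)
      dmat <- rbind(dmat, add)
      alive_from <- c(alive_from, rep(k + 1L, np))
      dead_at <- c(dead_at, rep(NA_integer_, np))
      injured <- c(injured, rep(FALSE, np))
      vigour <- c(vigour, exp(stats::rnorm(np, 0, config$growth_tree_sd) -
                                config$growth_tree_sd^2 / 2))
    }
  }

  trees <- melt_tree_state(dmat, plot_ix, subplot, alive_from, dead_at,
                           plots$plot_id, yrs)
  internal <- do.call(rbind, internal[!vapply(internal, is.null, logical(1))])
  class(internal) <- c("survival_observations", "data.frame")
  structure(list(trees = trees, plots = plots, truth = truth,
                 injured_ids = sprintf("S%05d", which(injured)),
                 sim_observations = internal,
                 config = config, seed = seed),
            class = "synthetic_forest")
}

# period regime for an interval starting at start_year: the schedule's
# period when it is a survival interval, otherwise the period of the
# nearest later survival interval (period 1 before the earthquake)
default_period_lookup <- function(config, start_year) {
  sch <- tryCatch(
    if (identical(config$years, default_years())) default_schedule() else NULL,
    error = function(e) NULL)
  if (!is.null(sch)) {
    hit <- sch$intervals$period[sch$intervals$start_year == start_year]
    if (length(hit)) return(hit)
    later <- sch$intervals[sch$intervals$start_year > start_year, ]
    if (nrow(later)) return(later$period[1L])
    return(sch$intervals$period[nrow(sch$intervals)])
  }
  if (start_year < config$eq_year_start) 1L
  else if (start_year < config$eq_year_end) 2L
  else 3L
}

# neighbourhood basal area (m2/ha) for focal trees, from the current state
block_basal_area <- function(plot_ix, subplot, diam, n_plots) {
  ba_m2 <- pi * (diam / 2000)^2
  key <- plot_ix * 100L + subplot
  per_sub <- tapply(ba_m2, key, sum)
  out <- numeric(length(plot_ix))
  blocks <- lapply(1:16, subplot_block)
  for (s in 1:16) {
    sel <- subplot == s
    if (!any(sel)) next
    for (p in unique(plot_ix[sel])) {
      keys <- as.character(p * 100L + blocks[[s]])
      tot <- sum(per_sub[keys], na.rm = TRUE)
      out[sel & plot_ix == p] <- tot / neighbourhood_area_ha()
    }
  }
  out
}

melt_tree_state <- function(dmat, plot_ix, subplot, alive_from, dead_at,
                            plot_ids, yrs) {
  K <- length(yrs)
  n <- nrow(dmat)
  ids <- sprintf("S%05d", seq_len(n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    last <- if (is.na(dead_at[i])) K else dead_at[i]
    span <- seq.int(alive_from[i], last)
    status <- rep("alive", length(span))
    if (!is.na(dead_at[i])) status[length(status)] <- "dead"
    rows[[i]] <- data.frame(
      tree_id = ids[i], plot_id = plot_ids[plot_ix[i]],
      subplot = subplot[i], year = yrs[span],
      diameter_mm = dmat[i, span], status = status,
      imputed = FALSE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$tree_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tree_table", "data.frame")
  out
}

#' Add diameter measurement error to a synthetic dataset
#'
#' Observed diameters are the true diameters plus independent Gaussian
#' noise, so a slow-growing tree's computed growth can come out negative —
#' the small negative growths the analysis deliberately retains. A
#' configurable rate of gross recording errors (e.g. transposed digits)
#' perturbs one measurement of the affected trees far enough to trip the
#' growth outlier rule and exercise imputation.
#'
#' @param dataset A `synthetic_forest`.
#' @param sd_mm Measurement error sd (mm); 0 returns observed = true.
#' @param gross_rate Per-tree probability of one gross error.
#' @param gross_mm Magnitude of a gross error (mm, random sign).
#' @return The dataset with perturbed `trees` (true diameters kept in
#'   `trees_true`) and the affected tree ids in `gross_error_ids`.
#' @export
apply_measurement_error <- function(dataset, sd_mm, gross_rate = 0,
                                    gross_mm = 200) {
  stopifnot(sd_mm >= 0, gross_rate >= 0, gross_rate <= 1)
  trees <- dataset$trees
  obs <- trees
  has_d <- !is.na(obs$diameter_mm)
  if (sd_mm > 0)
    obs$diameter_mm[has_d] <- obs$diameter_mm[has_d] +
      stats::rnorm(sum(has_d), 0, sd_mm)
  gross_ids <- character()
  if (gross_rate > 0) {
    ids <- unique(obs$tree_id)
    hit <- ids[stats::runif(length(ids)) < gross_rate]
    for (id in hit) {
      ix <- which(obs$tree_id == id & !is.na(obs$diameter_mm))
      if (length(ix) < 2L) next
      pick <- ix[sample.int(length(ix), 1L)]
      obs$diameter_mm[pick] <- obs$diameter_mm[pick] +
        sample(c(-1, 1), 1L) * gross_mm
      gross_ids <- c(gross_ids, id)
    }
  }
  obs$diameter_mm[has_d] <- pmax(obs$diameter_mm[has_d], 1)
  dataset$trees_true <- trees
  dataset$trees <- obs
  dataset$gross_error_ids <- gross_ids
  dataset
}
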