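#' Assemble model-ready survival observations
#'
#' Builds one row per (tree x survival interval) for trees that are alive at
#' the interval start, located in one of the four central 5 m x 5 m subplots,
#' and have both growth windows computable (so, for example, a tree first
#' tagged in 1987 contributes its first observation for the 1999-2004
#' interval). Trees alive at the start but not recorded at the interval end
#' are excluded and logged, not treated as dead. Each row carries the
#' standardized covariates of the survival model: diameter and its square
#' (centred at 164 mm), neighbourhood basal area (centred at 50 m2/ha),
#' previous and lagged annual growth (mm/yr, uncentred), and the plot-level
#' covariates (log soil-available P centred at ln 14.88, landform index
#' centred at 20 degrees, elevation centred at 1000 m per 100 m, log
#' epicentre distance centred at ln 18.17 km).
#'
#' @param trees A cleaned `tree_table` (see [clean_tree_table()]).
#' @param plots A `plot_table`.
#' @param schedule A [measurement_schedule()].
#' @param config A [standardization_config()].
#' @return A `survival_observations` data frame (columns listed under
#'   [write_observations()]), sorted by tree and interval, with an
#'   `"exclusions"` attribute logging every tree-interval dropped because the
#'   end-of-interval status was unrecorded.
#' @export
assemble_observations <- function(trees, plots,
                                  schedule = default_schedule(),
                                  config = standardization_config()) {
  if (nrow(trees) == 0L)
    stop("empty tree table: nothing to assemble")
  yrs <- schedule$years
  dmat <- diameter_matrix(trees, yrs)
  smat <- status_matrix(trees, yrs)
  plot_of <- tree_plot_map(trees)
  sub_of <- tree_subplot_map(trees)
  ids <- rownames(dmat)

  pcov <- plots[match(plot_of[ids], plots$plot_id), , drop = FALSE]
  if (anyNA(pcov$plot_id))
    stop("tree table references plot ids missing from the plot table")
  soil_std <- standardize(pcov$soil_avP_ug_g, config, "soil_p")
  land_std <- standardize(pcov$landform_index, config, "landform")
  elev_std <- standardize(pcov$elevation_m, config, "elevation")
  dist_std <- standardize(pcov$epicentre_distance_km, config, "distance")

  central <- sub_of[ids] %in% central_subplots()
  rows <- list(); excl <- list()
  for (k in seq_len(nrow(schedule$intervals))) {
    iv <- schedule$intervals[k, ]
    w <- growth_windows(schedule, iv$start_year)
    if (is.null(w$previous) || is.null(w$lagged))
      stop("survival interval ", iv$start_year, "-", iv$end_year,
           " lacks growth windows under this schedule")
    s <- as.character(iv$start_year); e <- as.character(iv$end_year)
    p0 <- as.character(w$previous$start_year)
    l0 <- as.character(w$lagged$start_year)

    alive_s <- !is.na(smat[, s]) & smat[, s] == "alive" & !is.na(dmat[, s])
    windows_ok <- !is.na(dmat[, p0]) & !is.na(dmat[, l0])
    cand <- alive_s & windows_ok & central
    end_missing <- cand & is.na(smat[, e])
    if (any(end_missing))
      excl[[length(excl) + 1L]] <- data.frame(
        tree_id = ids[end_missing], start_year = iv$start_year,
        end_year = iv$end_year, reason = "status unrecorded at interval end",
        stringsAsFactors = FALSE)
    use <- cand & !is.na(smat[, e])
    if (!any(use)) next
    uid <- ids[use]

    ba <- local_ba_lookup(trees, iv$start_year)
    ba_vals <- ba[paste(plot_of[uid], sub_of[uid], sep = "\r")]
    ba_vals[is.na(ba_vals)] <- 0

    d_s <- dmat[use, s]
    d_std <- standardize(d_s, config, "diameter")
    g_prev <- (d_s - dmat[use, p0]) /
      (w$previous$end_year - w$previous$start_year)
    g_lag <- (dmat[use, p0] - dmat[use, l0]) /
      (w$lagged$end_year - w$lagged$start_year)

    rows[[length(rows) + 1L]] <- data.frame(
      tree_id = uid,
      plot_id = unname(plot_of[uid]),
      subplot = unname(sub_of[uid]),
      start_year = iv$start_year,
      end_year = iv$end_year,
      delta_t = iv$delta_t,
      period = iv$period,
      outcome = as.integer(smat[use, e] == "alive"),
      diameter_std = unname(d_std),
      diameter_sq_std = unname(d_std^2),
      local_ba_std = unname(standardize(ba_vals, config, "basal_area")),
      growth_prev = unname(standardize(g_prev, config, "growth")),
      growth_lag = unname(standardize(g_lag, config, "growth")),
      soil_p_std = soil_std[match(uid, ids)],
      landform_std = land_std[match(uid, ids)],
      elevation_std = elev_std[match(uid, ids)],
      distance_std = dist_std[match(uid, ids)],
      stringsAsFactors = FALSE)
  }
  obs <- if (length(rows)) do.call(rbind, rows) else
    stop("no survival observations could be assembled")
  obs <- obs[order(obs$tree_id, obs$start_year), , drop = FALSE]
  rownames(obs) <- NULL
  class(obs) <- c("survival_observations", "data.frame")
  attr(obs, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(tree_id = character(), start_year = integer(),
               end_year = integer(), reason = character(),
               stringsAsFactors = FALSE)
  obs
}

# internal: named vector of local basal area keyed "plot\rsubplot" for the
# four central subplots of every plot, at one measurement year
local_ba_lookup <- function(trees, year) {
  rows <- trees[trees$year == year & trees$status == "alive" &
                  !is.na(trees$diameter_mm), , drop = FALSE]
  ba_m2 <- pi * (rows$diameter_mm / 2000)^2
  key <- paste(rows$plot_id, rows$subplot, sep = "\r")
  per_sub <- tapply(ba_m2, key, sum)
  plots <- unique(rows$plot_id)
  out <- numeric(0)
  for (p in plots) {
    subs <- per_sub[paste(p, 1:16, sep = "\r")]
    subs[is.na(subs)] <- 0
    for (ctr in central_subplots()) {
      out[paste(p, ctr, sep = "\r")] <-
        sum(subs[subplot_block(ctr)]) / neighbourhood_area_ha()
    }
  }
  out
}

#' Clean a tree table and assemble survival observations
#'
#' Convenience wrapper: [clean_tree_table()] then
#' [assemble_observations()]. The cleaning log (flagged outliers,
#' imputations, exclusions) is attached as the `"cleaning"` attribute.
#'
#' @inheritParams assemble_observations
#' @return A `survival_observations` data frame.
#' @export
prepare_observations <- function(trees, plots,
                                 schedule = default_schedule(),
                                 config = standardization_config()) {
  cl <- clean_tree_table(trees, schedule)
  obs <- assemble_observations(cl$trees, plots, schedule, config)
  attr(obs, "cleaning") <- cl[c("flagged", "imputations", "exclusions")]
  obs
}
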