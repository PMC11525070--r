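#' Neighbourhood basal area around a subplot
#'
#' The competition covariate is the basal area (m2/ha) of all living trees
#' inside the 15 m x 15 m square centred on a tree's 5 m x 5 m subplot,
#' i.e. the 3 x 3 block of subplots around `subplot_index`. All plot trees
#' contribute, whatever their subplot; a tree contributes from the
#' measurement years at which it is recorded alive with a diameter, and
#' zero from the first measurement at which it is recorded dead. For edge
#' subplots the block is truncated at the plot boundary, but survival
#' observations are restricted to the four central subplots, whose block
#' always lies wholly inside the plot.
#'
#' @param plot_trees `tree_table` rows for a single plot (all 16 subplots).
#' @param subplot_index Focal subplot, 1..16.
#' @param year Measurement year.
#' @return Basal area in m2 per ha (block area 0.0225 ha).
#' @examples
#' # one living 164 mm tree in the block: pi * 0.082^2 / 0.0225 = 0.9389
#' @export
local_basal_area <- function(plot_trees, subplot_index, year) {
  block <- subplot_block(subplot_index)
  rows <- plot_trees[plot_trees$year == year &
                       plot_trees$status == "alive" &
                       plot_trees$subplot %in% block &
                       !is.na(plot_trees$diameter_mm), , drop = FALSE]
  sum(pi * (rows$diameter_mm / 2000)^2) / neighbourhood_area_ha()
}

#' Plot basal-area time series
#'
#' Whole-plot basal area (m2/ha, plot area 0.04 ha) per measurement year,
#' averaged across plots with its standard error (sd across plots divided
#' by the square root of the number of plots). This is the stand-level
#' recovery/decline trajectory used to situate the survival periods.
#'
#' @param trees A `tree_table`.
#' @param plots A `plot_table` (defines the set of plots; plots with no
#'   living trees in a year contribute 0 for that year).
#' @param schedule A [measurement_schedule()].
#' @return Data frame with columns `year`, `mean_ba`, `se_ba`, `n_plots`.
#' @export
basal_area_series <- function(trees, plots, schedule = default_schedule()) {
  yrs <- schedule$years
  pl <- plots$plot_id
  out <- data.frame(year = yrs, mean_ba = NA_real_, se_ba = NA_real_,
                    n_plots = length(pl))
  for (k in seq_along(yrs)) {
    rows <- trees[trees$year == yrs[k] & trees$status == "alive" &
                    !is.na(trees$diameter_mm), , drop = FALSE]
    ba_by_plot <- vapply(pl, function(p)
      sum(pi * (rows$diameter_mm[rows$plot_id == p] / 2000)^2) / plot_area_ha(),
      numeric(1))
    out$mean_ba[k] <- mean(ba_by_plot)
    out$se_ba[k] <- stats::sd(ba_by_plot) / sqrt(length(pl))
  }
  out
}
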