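#' Annual diameter growth over a measurement window
#'
#' Growth is the diameter change divided by the window length in years.
#' Negative values are allowed and deliberately retained downstream: small
#' diameter decreases can be routine measurement error, and dropping them
#' would bias growth upward in a slow-growing species.
#'
#' @param d_start,d_end Diameters (mm) at window start and end.
#' @param delta_t Window length in years (> 0).
#' @return Growth rate in mm per year. A missing diameter is an error (the
#'   caller must impute first, not silently drop the tree).
#' @examples
#' interval_growth(100, 110, 5)  # 2
#' interval_growth(100, 95, 5)   # -1, retained
#' @export
interval_growth <- function(d_start, d_end, delta_t) {
  if (any(delta_t <= 0)) stop("delta_t must be > 0")
  if (any(is.na(d_start)) || any(is.na(d_end)))
    stop("missing diameter: imputation required before computing growth")
  (d_end - d_start) / delta_t
}

# Per-tree growth rates over all consecutive measurement windows where both
# diameters are recorded. Returns tree_id, plot_id, start_year, end_year,
# rate (mm/yr).
tree_growth_rates <- function(trees, schedule = default_schedule()) {
  yrs <- schedule$years
  wide <- diameter_matrix(trees, yrs)
  out <- vector("list", length(yrs) - 1L)
  plot_of <- tree_plot_map(trees)
  for (k in seq_len(length(yrs) - 1L)) {
    d0 <- wide[, k]; d1 <- wide[, k + 1L]
    ok <- !is.na(d0) & !is.na(d1)
    if (!any(ok)) next
    out[[k]] <- data.frame(
      tree_id = rownames(wide)[ok],
      plot_id = unname(plot_of[rownames(wide)[ok]]),
      start_year = yrs[k], end_year = yrs[k + 1L],
      rate = (d1[ok] - d0[ok]) / (yrs[k + 1L] - yrs[k]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(tree_id = character(), plot_id = character(),
                      start_year = integer(), end_year = integer(),
                      rate = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Flag trees with physically implausible growth rates
#'
#' A tree is flagged when any of its window growth rates is greater than
#' 10 mm/yr or less than -3 mm/yr (strict inequalities: exactly 10.0 or
#' -3.0 is not flagged). Flagged trees have the offending diameter imputed
#' rather than being dropped.
#'
#' @param rates Data frame with columns `tree_id` and `rate` (mm/yr), e.g.
#'   from the per-window rates computed internally by [clean_tree_table()].
#' @param upper,lower Flagging thresholds (mm/yr).
#' @return Character vector of unique flagged tree ids.
#' @export
flag_growth_outliers <- function(rates, upper = 10, lower = -3) {
  bad <- rates$rate > upper | rates$rate < lower
  sort(unique(rates$tree_id[bad & !is.na(bad)]))
}

#' Impute a diameter from plot-level growth summaries
#'
#' Predicts the diameter of `tree_id` at `year` as the tree's nearest
#' reliable measurement plus the median growth rate of same-plot trees in
#' the same diameter tercile over the same window, times the elapsed years.
#' Terciles are formed from the plot's diameters at the anchor year;
#' trees flagged as growth outliers are excluded from the summaries. When
#' fewer than two tercile trees have the window recorded, the whole plot's
#' median is used instead.
#'
#' @param trees A `tree_table`.
#' @param tree_id,year The tree and measurement year to impute.
#' @param schedule A [measurement_schedule()].
#' @param exclude_trees Tree ids excluded from the plot summaries (e.g.
#'   outlier-flagged trees).
#' @return Imputed diameter (mm), or `NA` with attribute `"reason"` when no
#'   reliable anchor measurement exists.
#' @examples
#' # a tree measured 100 mm in 1983 with plot-tercile median growth
#' # 1.5 mm/yr over 1983-1987 imputes to 106 mm in 1987
#' @export
impute_diameter <- function(trees, tree_id, year, schedule = default_schedule(),
                            exclude_trees = character()) {
  yrs <- schedule$years
  year <- as.integer(year)
  rows <- trees[trees$tree_id == tree_id, , drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown tree_id: ", tree_id)
  anchors <- rows$year[!is.na(rows$diameter_mm) & rows$year != year]
  if (length(anchors) == 0L) {
    out <- NA_real_
    attr(out, "reason") <- "no reliable anchor measurement"
    return(out)
  }
  # nearest reliable measurement; earlier year wins a tie
  anchor_year <- anchors[order(abs(anchors - year), anchors)][1L]
  anchor_d <- rows$diameter_mm[rows$year == anchor_year][1L]
  plot_id <- rows$plot_id[1L]

  mates <- trees[trees$plot_id == plot_id &
                   !trees$tree_id %in% c(tree_id, exclude_trees), , drop = FALSE]
  d_anchor <- mates$diameter_mm[mates$year == anchor_year]
  id_anchor <- mates$tree_id[mates$year == anchor_year]
  keep <- !is.na(d_anchor)
  d_anchor <- d_anchor[keep]; id_anchor <- id_anchor[keep]

  lo <- min(anchor_year, year); hi <- max(anchor_year, year)
  win_years <- yrs[yrs >= lo & yrs <= hi]
  rate_of <- function(ids) {
    m <- mates[mates$tree_id %in% ids & mates$year %in% c(lo, hi), , drop = FALSE]
    sp <- split(m, m$tree_id)
    r <- vapply(sp, function(g) {
      d0 <- g$diameter_mm[g$year == lo]; d1 <- g$diameter_mm[g$year == hi]
      if (length(d0) == 1L && length(d1) == 1L && !is.na(d0) && !is.na(d1))
        (d1 - d0) / (hi - lo) else NA_real_
    }, numeric(1))
    r[!is.na(r)]
  }
  med <- NA_real_
  if (length(d_anchor) >= 3L) {
    br <- stats::quantile(d_anchor, c(1 / 3, 2 / 3), names = FALSE, type = 7)
    terc <- findInterval(anchor_d, br) + 1L
    in_terc <- id_anchor[findInterval(d_anchor, br) + 1L == terc]
    r <- rate_of(in_terc)
    if (length(r) >= 2L) med <- stats::median(r)
  }
  if (is.na(med)) {
    r <- rate_of(unique(mates$tree_id))
    if (length(r) >= 1L) med <- stats::median(r)
  }
  if (is.na(med)) med <- 0  # lone-tree plot: carry the anchor forward
  anchor_d + med * (year - anchor_year)
}

#' Clean a tree table: flag outliers and impute diameters
#'
#' Applies the growth quality-control rules to a whole table: window growth
#' rates outside (-3, 10) mm/yr flag a tree, and the chronologically later
#' diameter of the offending window is imputed; interior missing diameters
#' of otherwise-recorded trees are imputed the same way (see
#' [impute_diameter()]). Trees for which imputation is impossible are
#' excluded with a logged reason.
#'
#' @param trees A `tree_table`.
#' @param schedule A [measurement_schedule()].
#' @return List with elements `trees` (cleaned table; imputed rows have
#'   `imputed = TRUE`), `flagged` (outlier tree ids), `imputations` (data
#'   frame tree_id/year/old/new) and `exclusions` (data frame
#'   tree_id/reason).
#' @export
clean_tree_table <- function(trees, schedule = default_schedule()) {
  rates <- tree_growth_rates(trees, schedule)
  flagged <- flag_growth_outliers(rates)
  imput <- list(); excl <- list()

  # interior missing diameters (status alive but diameter absent between
  # recorded measurements)
  need <- list()
  for (id in unique(trees$tree_id)) {
    rows <- trees[trees$tree_id == id, , drop = FALSE]
    alive <- rows[rows$status == "alive", , drop = FALSE]
    if (nrow(alive) == 0L) next
    span <- schedule$years[schedule$years >= min(alive$year) &
                             schedule$years <= max(alive$year)]
    got <- rows$year[!is.na(rows$diameter_mm)]
    miss <- setdiff(span, got)
    for (y in miss) need[[length(need) + 1L]] <- list(id = id, year = y)
  }
  # offending window ends for flagged trees (processed chronologically)
  for (id in flagged) {
    r <- rates[rates$tree_id == id, , drop = FALSE]
    r <- r[order(r$start_year), , drop = FALSE]
    bad <- r$rate > 10 | r$rate < -3
    for (y in r$end_year[bad])
      need[[length(need) + 1L]] <- list(id = id, year = y)
  }

  out <- trees
  for (nd in need) {
    val <- impute_diameter(out, nd$id, nd$year, schedule,
                           exclude_trees = flagged)
    if (is.na(val)) {
      excl[[length(excl) + 1L]] <-
        data.frame(tree_id = nd$id, reason = attr(val, "reason"),
                   stringsAsFactors = FALSE)
      next
    }
    ix <- which(out$tree_id == nd$id & out$year == nd$year)
    if (length(ix) == 0L) {
      ref <- out[out$tree_id == nd$id, , drop = FALSE][1L, , drop = FALSE]
      ref$year <- as.integer(nd$year); ref$diameter_mm <- val
      ref$status <- "alive"; ref$imputed <- TRUE
      old <- NA_real_
      out <- rbind(out, ref)
    } else {
      old <- out$diameter_mm[ix[1L]]
      out$diameter_mm[ix[1L]] <- val
      out$imputed[ix[1L]] <- TRUE
    }
    imput[[length(imput) + 1L]] <-
      data.frame(tree_id = nd$id, year = nd$year, old = old, new = val,
                 stringsAsFactors = FALSE)
  }
  excl_df <- if (length(excl)) unique(do.call(rbind, excl)) else
    data.frame(tree_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  out <- out[!out$tree_id %in% excl_df$tree_id, , drop = FALSE]
  out <- out[order(out$tree_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tree_table", "data.frame")
  list(trees = out, flagged = flagged,
       imputations = if (length(imput)) do.call(rbind, imput) else
         data.frame(tree_id = character(), year = integer(), old = numeric(),
                    new = numeric(), stringsAsFactors = FALSE),
       exclusions = excl_df)
}

# internal: trees x years diameter matrix (rownames = tree ids)
diameter_matrix <- function(trees, years) {
  ids <- unique(trees$tree_id)
  m <- matrix(NA_real_, length(ids), length(years),
              dimnames = list(ids, years))
  ix <- cbind(match(trees$tree_id, ids), match(trees$year, years))
  ok <- !is.na(ix[, 2L])
  m[ix[ok, , drop = FALSE]] <- trees$diameter_mm[ok]
  m
}

# internal: alive/dead status matrix ("alive", "dead" or NA)
status_matrix <- function(trees, years) {
  ids <- unique(trees$tree_id)
  m <- matrix(NA_character_, length(ids), length(years),
              dimnames = list(ids, years))
  ix <- cbind(match(trees$tree_id, ids), match(trees$year, years))
  ok <- !is.na(ix[, 2L])
  m[ix[ok, , drop = FALSE]] <- trees$status[ok]
  m
}

tree_plot_map <- function(trees) {
  first <- !duplicated(trees$tree_id)
  stats::setNames(trees$plot_id[first], trees$tree_id[first])
}

tree_subplot_map <- function(trees) {
  first <- !duplicated(trees$tree_id)
  stats::setNames(trees$subplot[first], trees$tree_id[first])
}
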