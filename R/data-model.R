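#' Read a tagged-tree remeasurement table
#'
#' The interchange format is long-form CSV with one row per tree per
#' measurement: columns `tree_id`, `plot_id`, `subplot`, `year`,
#' `diameter_mm`, `status` (`"alive"` or `"dead"`). A header row is
#' mandatory. Years with no row for a tree are treated as missing data (or,
#' before the first row, as not-yet-tagged), never as zero diameter. A
#' `species` column is tolerated but ignored: the analysis is single-species.
#'
#' Validation enforces the absorbing-death rule (once dead, never again
#' alive) and warns when a tree's first recorded diameter is below the 30 mm
#' minimum tagging size.
#'
#' @param path CSV file path.
#' @param schedule A [measurement_schedule()]; rows with years outside the
#'   schedule are an error.
#' @return A `tree_table`: a data frame with the columns above (plus logical
#'   `imputed`, initially `FALSE`), sorted by tree and year.
#' @export
read_tree_table <- function(path, schedule = default_schedule()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(empty_tree_table())
  needed <- c("tree_id", "plot_id", "subplot", "year", "diameter_mm", "status")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("tree table is missing columns: ", paste(missing_cols, collapse = ", "))
  df <- df[needed]
  bad <- which(is.na(df$tree_id) | is.na(df$year) | is.na(df$status) |
                 !df$status %in% c("alive", "dead"))
  if (length(bad))
    stop("malformed tree table row at data line ", bad[1L],
         " (tree_id/year missing or status not alive/dead)")
  df$subplot <- as.integer(df$subplot)
  df$year <- as.integer(df$year)
  df$diameter_mm <- as.numeric(df$diameter_mm)
  if (any(df$subplot < 1L | df$subplot > 16L, na.rm = TRUE))
    stop("subplot index outside 1..16")
  if (!all(df$year %in% schedule$years))
    stop("tree table contains years not in the measurement schedule")
  df$imputed <- FALSE
  df <- df[order(df$tree_id, df$year), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("tree_table", "data.frame")
  validate_tree_table(df)
  df
}

empty_tree_table <- function() {
  df <- data.frame(tree_id = character(), plot_id = character(),
                   subplot = integer(), year = integer(),
                   diameter_mm = numeric(), status = character(),
                   imputed = logical(), stringsAsFactors = FALSE)
  class(df) <- c("tree_table", "data.frame")
  df
}

#' Validate a tree table
#'
#' Checks the absorbing-death rule (a tree recorded dead is never later
#' recorded alive) and the 30 mm minimum tagging size (violations produce a
#' warning, not an error, since imputation may legitimately produce smaller
#' values).
#'
#' @param trees A `tree_table`.
#' @return `trees`, invisibly; errors/warnings on violations.
#' @export
validate_tree_table <- function(trees) {
  if (nrow(trees) == 0L) return(invisible(trees))
  sp <- split(seq_len(nrow(trees)), trees$tree_id)
  first_d <- vapply(sp, function(ix) trees$diameter_mm[ix[1L]], numeric(1))
  for (id in names(sp)) {
    st <- trees$status[sp[[id]]]
    dead_at <- which(st == "dead")
    if (length(dead_at) && any(st[seq.int(min(dead_at), length(st))] == "alive"))
      stop("tree ", id, " is recorded alive after being recorded dead")
  }
  small <- names(first_d)[!is.na(first_d) & first_d < 30]
  small <- small[!vapply(small, function(id)
    any(trees$imputed[sp[[id]]][1L]), logical(1))]
  if (length(small))
    warning(length(small), " tree(s) first tagged below the 30 mm minimum ",
            "diameter (e.g. ", small[1L], ")")
  invisible(trees)
}

#' Read a plot covariate table
#'
#' CSV with one row per plot: `plot_id`, `transect_id`, `elevation_m`,
#' `slope_deg`, `landform_index`, `soil_avP_ug_g`,
#' `epicentre_distance_km`. Soil-available P and epicentre distance must be
#' strictly positive (both are log-transformed during standardization);
#' elevations outside the 640-1417 m study range produce a warning.
#'
#' @param path CSV file path.
#' @return A `plot_table` data frame.
#' @export
read_plot_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("plot_id", "transect_id", "elevation_m", "slope_deg",
              "landform_index", "soil_avP_ug_g", "epicentre_distance_km")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("plot table is missing columns: ", paste(missing_cols, collapse = ", "))
  df <- df[needed]
  num <- needed[-(1:2)]
  df[num] <- lapply(df[num], as.numeric)
  if (anyDuplicated(df$plot_id)) stop("duplicate plot_id in plot table")
  if (any(df$soil_avP_ug_g <= 0, na.rm = TRUE))
    stop("soil_avP_ug_g must be > 0")
  if (any(df$epicentre_distance_km <= 0, na.rm = TRUE))
    stop("epicentre_distance_km must be > 0")
  if (any(df$elevation_m < 640 | df$elevation_m > 1417, na.rm = TRUE))
    warning("plot elevations outside the 640-1417 m study range")
  class(df) <- c("plot_table", "data.frame")
  df
}

#' Write and read survival observation tables
#'
#' Survival observations (see [assemble_observations()]) round-trip through
#' CSV losslessly: numeric fields are written with full double precision and
#' compare equal to at least 1e-9 relative tolerance on read-back. Signs of
#' small negative growth rates are preserved; such trees are deliberately
#' retained in the models because small diameter decreases can be routine
#' measurement error.
#'
#' @param observations Data frame of class `survival_observations`.
#' @param path Output CSV path.
#' @return `write_observations`: `path`, invisibly. `read_observations`: the
#'   observations data frame.
#' @export
write_observations <- function(observations, path) {
  df <- as.data.frame(observations)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- observation_columns()
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("observations table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  int_cols <- c("start_year", "end_year", "period", "outcome", "subplot")
  df[int_cols] <- lapply(df[int_cols], as.integer)
  if (!all(df$outcome %in% 0:1)) stop("outcome must be 0 or 1")
  if (!all(df$period %in% 1:3)) stop("period must be 1, 2 or 3")
  class(df) <- c("survival_observations", "data.frame")
  df
}

observation_columns <- function() {
  c("tree_id", "plot_id", "subplot", "start_year", "end_year", "delta_t",
    "period", "outcome", "diameter_std", "diameter_sq_std", "local_ba_std",
    "growth_prev", "growth_lag", "soil_p_std", "landform_std",
    "elevation_std", "distance_std")
}
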