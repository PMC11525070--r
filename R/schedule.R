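#' Measurement schedule and survival intervals
#'
#' A measurement schedule records the calendar years at which a plot network
#' was remeasured, and the subset of between-measurement intervals used as
#' survival intervals, each tagged with a survival-period index. Coefficients
#' of the survival model are constant within a period but may differ between
#' periods, so the period index is what links an observation to its
#' coefficient regime.
#'
#' The default schedule is the eight measurements 1974, 1978, 1983, 1987,
#' 1993, 1999, 2004 and 2009, with five survival intervals: 1983-1987 and
#' 1987-1993 in period 1 (pre-earthquake), 1993-1999 in period 2 (0-5 years
#' post-earthquake), and 1999-2004 and 2004-2009 in period 3 (5+ years
#' post-earthquake). The first two between-measurement intervals are not
#' survival intervals; they supply the growth windows for the first survival
#' interval.
#'
#' @param years Strictly increasing integer vector of measurement years.
#' @param intervals Data frame with columns `start_year`, `end_year`,
#'   `period` giving the survival intervals. Both endpoints must be schedule
#'   years and `period` must be in 1..3. If `NULL` and `years` is the default
#'   schedule, the default five intervals are used.
#' @return An object of class `measurement_schedule`: a list with elements
#'   `years` and `intervals` (the intervals data frame gains a `delta_t`
#'   column).
#' @examples
#' sch <- default_schedule()
#' sch$intervals
#' @export
measurement_schedule <- function(years, intervals = NULL) {
  years <- as.integer(years)
  if (length(years) < 2L || any(diff(years) <= 0L))
    stop("schedule years must be strictly increasing")
  if (is.null(intervals)) {
    if (identical(years, default_years())) {
      intervals <- data.frame(
        start_year = c(1983L, 1987L, 1993L, 1999L, 2004L),
        end_year   = c(1987L, 1993L, 1999L, 2004L, 2009L),
        period     = c(1L, 1L, 2L, 3L, 3L)
      )
    } else {
      stop("intervals must be supplied for a non-default schedule")
    }
  }
  intervals <- as.data.frame(intervals)
  needed <- c("start_year", "end_year", "period")
  if (!all(needed %in% names(intervals)))
    stop("intervals needs columns start_year, end_year, period")
  intervals$start_year <- as.integer(intervals$start_year)
  intervals$end_year <- as.integer(intervals$end_year)
  intervals$period <- as.integer(intervals$period)
  if (!all(intervals$start_year %in% years) ||
      !all(intervals$end_year %in% years))
    stop("survival interval endpoints must be schedule years")
  if (any(intervals$end_year <= intervals$start_year))
    stop("survival intervals must have end_year > start_year")
  if (!all(intervals$period %in% 1:3))
    stop("period index must be 1, 2 or 3")
  intervals$delta_t <- intervals$end_year - intervals$start_year
  structure(list(years = years, intervals = intervals),
            class = "measurement_schedule")
}

default_years <- function() c(1974L, 1978L, 1983L, 1987L, 1993L, 1999L, 2004L, 2009L)

#' @rdname measurement_schedule
#' @export
default_schedule <- function() measurement_schedule(default_years())

#' @export
print.measurement_schedule <- function(x, ...) {
  cat("Measurement schedule:", paste(x$years, collapse = ", "), "\n")
  cat(nrow(x$intervals), "survival intervals:\n")
  print(x$intervals, row.names = FALSE)
  invisible(x)
}

#' Growth windows aligned to a survival interval
#'
#' For a survival interval starting at measurement year `start_year`, the
#' *previous* growth window is the between-measurement interval ending at
#' `start_year`, and the *lagged* window is the one before that. For example,
#' under the default schedule the 1983-1987 survival interval uses 1978-1983
#' as previous growth and 1974-1978 as lagged growth.
#'
#' @param schedule A [measurement_schedule()].
#' @param start_year Survival-interval start year (a schedule year).
#' @return List with data frames `previous` and `lagged`, each with
#'   `start_year`, `end_year`, or `NULL` for a window that would precede the
#'   first measurement.
#' @export
growth_windows <- function(schedule, start_year) {
  yrs <- schedule$years
  i <- match(as.integer(start_year), yrs)
  if (is.na(i)) stop("start_year is not a schedule year")
  prev <- if (i >= 2L) list(start_year = yrs[i - 1L], end_year = yrs[i]) else NULL
  lag <- if (i >= 3L) list(start_year = yrs[i - 2L], end_year = yrs[i - 1L]) else NULL
  list(previous = prev, lagged = lag)
}

#' Plot geometry constants
#'
#' Plots are 20 m x 20 m (0.04 ha), divided into a 4 x 4 grid of 5 m x 5 m
#' subplots indexed 1..16 in row-major order. The four central subplots are
#' 6, 7, 10 and 11. A tree's neighbourhood is the 3 x 3 block of subplots
#' (15 m x 15 m, 0.0225 ha) centred on its subplot.
#'
#' @name plot_geometry
#' @return `plot_area_ha()` returns 0.04; `neighbourhood_area_ha()` returns
#'   0.0225; `central_subplots()` returns `c(6L, 7L, 10L, 11L)`;
#'   `subplot_block(i)` returns the subplot indices of the 3 x 3 block around
#'   subplot `i` (truncated at the plot boundary for edge subplots).
NULL

#' @rdname plot_geometry
#' @export
plot_area_ha <- function() 0.04

#' @rdname plot_geometry
#' @export
neighbourhood_area_ha <- function() 0.0225

#' @rdname plot_geometry
#' @export
central_subplots <- function() c(6L, 7L, 10L, 11L)

#' @rdname plot_geometry
#' @param i Subplot index, 1..16.
#' @export
subplot_block <- function(i) {
  i <- as.integer(i)
  if (i < 1L || i > 16L) stop("subplot index must be in 1..16")
  row <- (i - 1L) %/% 4L + 1L
  col <- (i - 1L) %% 4L + 1L
  rows <- row + (-1:1); cols <- col + (-1:1)
  rows <- rows[rows >= 1L & rows <= 4L]
  cols <- cols[cols >= 1L & cols <= 4L]
  as.integer(outer(rows, cols, function(r, co) (r - 1L) * 4L + co))
}
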