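# Daily flow series container: a plain tibble (date, discharge) carrying
# gauge metadata as attributes, so it pipes through dplyr untouched.

#' Construct a daily flow series
#'
#' @param date `Date` vector, strictly increasing.
#' @param discharge daily mean discharge, non-negative or `NA` for missing.
#' @param gauge_id gauge identifier.
#' @param units `"cfs"` or `"cms"`.
#' @param drainage_area upstream drainage area in km2 (optional; required by
#'   the per-area metrics MA41 and MH20).
#' @return a tibble of class `daily_flow` with columns `date`, `discharge`.
#' @export
daily_flow_series <- function(date, discharge, gauge_id = NA_character_,
                              units = c("cfs", "cms"), drainage_area = NA_real_) {
  units <- match.arg(units)
  if (!inherits(date, "Date")) abort("`date` must be a Date vector", class = "eflowalt_input_error")
  if (length(date) != length(discharge)) {
    abort("`date` and `discharge` lengths differ", class = "eflowalt_input_error")
  }
  if (is.unsorted(date, strictly = TRUE)) {
    abort("dates must be strictly increasing", class = "eflowalt_input_error")
  }
  if (any(discharge < 0, na.rm = TRUE)) {
    abort("negative discharge values are not allowed; mark missing as NA",
          class = "eflowalt_input_error")
  }
  out <- tibble::tibble(date = date, discharge = as.numeric(discharge))
  attr(out, "gauge_id") <- gauge_id
  attr(out, "units") <- units
  attr(out, "drainage_area") <- drainage_area
  class(out) <- c("daily_flow", class(out))
  out
}

flow_attr <- function(series, what) attr(series, what, exact = TRUE)

# Re-attach flow metadata after dplyr operations strip attributes.
restore_flow_attrs <- function(out, template) {
  attr(out, "gauge_id") <- flow_attr(template, "gauge_id")
  attr(out, "units") <- flow_attr(template, "units")
  attr(out, "drainage_area") <- flow_attr(template, "drainage_area")
  if (!inherits(out, "daily_flow")) class(out) <- c("daily_flow", class(out))
  out
}

#' Screen a daily flow record for complete water years
#'
#' A water year is retained when it has at most `max_missing_days` missing
#' daily values (absent dates and `NA` both count as missing against the full
#' 365/366-day calendar of that water year; 29 February is not expected when
#' `drop_leap` is `TRUE`). A gauge passes screening only when at least
#' `min_years` water years survive.
#'
#' @param series a `daily_flow` tibble.
#' @param max_missing_days maximum missing days tolerated per water year.
#' @param min_years minimum number of complete water years required.
#' @param drop_leap if `TRUE`, 29 February is dropped and never counted.
#' @return the series restricted to complete water years, with attributes
#'   `screen_report` (per-year tibble) and `n_complete_years`.
#' @export
screen_record <- function(series, max_missing_days = 30L, min_years = 15L,
                          drop_leap = TRUE) {
  if (nrow(series) == 0L) abort("empty flow series", class = "eflowalt_input_error")
  df <- series
  if (drop_leap) df <- df[format(df$date, "%m-%d") != "02-29", , drop = FALSE]
  wy <- water_year(df$date)
  obs <- tapply(!is.na(df$discharge), wy, sum)
  yrs <- as.integer(names(obs))
  expected <- vapply(yrs, function(y) {
    n <- as.integer(as.Date(sprintf("%d-09-30", y)) - as.Date(sprintf("%d-10-01", y - 1L))) + 1L
    if (drop_leap && n == 366L) n <- 365L
    n
  }, integer(1))
  report <- tibble::tibble(
    water_year = yrs,
    n_days = as.integer(obs),
    n_missing = expected - as.integer(obs),
    kept = expected - as.integer(obs) <= max_missing_days
  )
  keep_years <- report$water_year[report$kept]
  if (length(keep_years) < min_years) {
    abort(
      sprintf("screening failure: %d complete water years (< %d required)",
              length(keep_years), min_years),
      class = "eflowalt_screening_error",
      report = report
    )
  }
  out <- df[wy %in% keep_years & !is.na(df$discharge), , drop = FALSE]
  out <- restore_flow_attrs(out, series)
  attr(out, "screen_report") <- report
  attr(out, "n_complete_years") <- length(keep_years)
  out
}

#' Per-year screening report of a screened series
#' @param series output of [screen_record()].
#' @return tibble with one row per water year in the raw record.
#' @export
screen_report <- function(series) attr(series, "screen_report", exact = TRUE)
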