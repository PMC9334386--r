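# Shared helpers: calendars, scaling, rank AUC.

#' Water-year label for a date
#'
#' Water years run 1 October to 30 September and are labelled by the ending
#' calendar year (USGS convention), so 2000-10-01 falls in water year 2001.
#'
#' @param date a `Date` vector.
#' @param start_month first month of the water year (default 10).
#' @return integer vector of water-year labels.
#' @export
water_year <- function(date, start_month = 10L) {
  stopifnot(inherits(date, "Date"))
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  ifelse(m >= start_month, y + 1L, y)
}

#' Daily date sequence on the fixed 365-day synthetic calendar
#'
#' Consecutive calendar dates with 29 February removed, so every year has
#' exactly 365 days; starting at a water-year boundary gives whole water
#' years.
#'
#' @param n_years number of 365-day years.
#' @param start first date (default 2000-10-01, a water-year start).
#' @return `Date` vector of length `n_years * 365`.
#' @export
synthetic_dates <- function(n_years, start = as.Date("2000-10-01")) {
  seq_days_no_leap(start, as.integer(n_years) * 365L)
}

# Calendar sequence with Feb 29 removed, so every year has exactly 365 days.
seq_days_no_leap <- function(start, n_days) {
  d <- seq(start, by = "day", length.out = n_days + ceiling(n_days / 365) + 2L)
  d <- d[!(format(d, "%m-%d") == "02-29")]
  d[seq_len(n_days)]
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Min-max scale to [0, 1]; constant input maps to 0 (with optional warning).
minmax01 <- function(x, warn_constant = FALSE, what = "values") {
  rng <- range(x, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[1] == rng[2]) {
    if (warn_constant) warn(sprintf("constant %s: min-max scaling returns zeros", what))
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Rank-based AUC (Mann-Whitney with midranks)
#'
#' Probability that a randomly chosen positive case ranks above a randomly
#' chosen negative case under the score `pred`; ties contribute 1/2.
#'
#' @param pred numeric scores.
#' @param label logical or 0/1 vector; `TRUE`/1 is the positive class.
#' @return AUC in \[0, 1\], or `NA` if only one class is present.
#' @export
rank_auc <- function(pred, label) {
  label <- as.logical(label)
  keep <- is.finite(pred) & !is.na(label)
  pred <- pred[keep]; label <- label[keep]
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(pred, ties.method = "average")
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Deterministic RNG scoping: run expr under a seed, restore global state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive a stream of sub-seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
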