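# The 41-index hydrologic metric engine. Index codes follow the standard
# magnitude/duration/frequency/timing/rate naming (MA, ML, MH, DL, DH, FL,
# FH, TA, RA) used throughout the indicators-of-hydrologic-alteration
# literature. All annual statistics are computed over water years.

#' Metric codes computed by the engine
#' @return character vector of the 41 index codes.
#' @export
metric_codes <- function() {
  c("MA1", "MA2", "MA3", paste0("MA", 12:23), "MA41", "ML17", "ML19", "MH20",
    paste0("DL", 1:5), "DL16", "DL18", paste0("DH", 1:5), "DH15",
    "FL1", "FH1", "FH6", "FH7", "TA1", "TA2", "RA1", "RA3", "RA8")
}

rolling_window_sizes <- c(1L, 3L, 7L, 30L, 90L)

# internal: split discharge by water year, in date order
.year_split <- function(series) {
  split(series$discharge, water_year(series$date))
}

# trailing rolling mean fully contained in the vector; length n - w + 1
.roll_mean <- function(x, w) {
  if (length(x) < w) return(numeric(0))
  if (w == 1L) return(x)
  cs <- cumsum(c(0, x))
  (cs[(w + 1L):length(cs)] - cs[seq_len(length(cs) - w)]) / w
}

# maximal runs of TRUE; returns integer lengths of each run
.run_lengths <- function(flag) {
  r <- rle(flag)
  r$lengths[r$values]
}

#' Magnitude metrics (MA, ML, MH families)
#'
#' MA1 mean and MA2 median of daily flow; MA3 coefficient of variation of
#' daily flows in percent; MA12-MA23 mean monthly flows January through
#' December; MA41 mean annual runoff (annual-mean flow over drainage area);
#' ML17 mean of annual 7-day-minimum / annual-mean ratios; ML19 mean of
#' annual (1-day minimum / annual mean) x 100; MH20 mean annual 1-day
#' maximum divided by drainage area.
#'
#' @param series a screened `daily_flow` series (see [screen_record()]).
#' @return one-row tibble of metric values.
#' @export
magnitude_metrics <- function(series) {
  q <- series$discharge
  area <- flow_attr(series, "drainage_area")
  mon <- as.integer(format(series$date, "%m"))
  monthly <- vapply(1:12, function(m) mean(q[mon == m]), numeric(1))
  yrs <- .year_split(series)
  ann_mean <- vapply(yrs, mean, numeric(1))
  min7 <- vapply(yrs, function(x) {
    r <- .roll_mean(x, 7L); if (length(r)) min(r) else NA_real_
  }, numeric(1))
  need_area <- function(code) {
    if (is.na(area) || is.null(area)) {
      abort(sprintf("%s requires a drainage_area attribute", code),
            class = "eflowalt_input_error")
    }
  }
  out <- c(
    MA1 = mean(q),
    MA2 = median(q),
    MA3 = if (mean(q) > 0) 100 * sd(q) / mean(q) else 0,
    setNames(monthly, paste0("MA", 12:23)),
    MA41 = { need_area("MA41"); mean(ann_mean) / area },
    ML17 = mean(min7 / ann_mean, na.rm = TRUE),
    ML19 = mean(vapply(yrs, min, numeric(1)) / ann_mean) * 100,
    MH20 = { need_area("MH20"); mean(vapply(yrs, max, numeric(1))) / area }
  )
  tibble::as_tibble(as.list(out))
}

#' Duration metrics (DL, DH families)
#'
#' DL1-DL5 (DH1-DH5): mean across years of the annual minimum (maximum) of
#' 1-, 3-, 7-, 30- and 90-day trailing means of daily discharge; windows are
#' fully contained within a water year and years shorter than the window are
#' skipped for that index. DL16 (DH15): mean across years of the median
#' duration of pulses below the low (above the high) pulse threshold. DL18:
#' mean annual count of zero-flow days, prorated to a 365-day year.
#'
#' @inheritParams magnitude_metrics
#' @param thresholds low/high pulse thresholds; see [pulse_thresholds()].
#' @return one-row tibble of metric values.
#' @export
duration_metrics <- function(series, thresholds = pulse_thresholds(series)) {
  yrs <- .year_split(series)
  if (any(vapply(yrs, length, integer(1)) < max(rolling_window_sizes))) {
    # not an error: short years are skipped per-window below, but a window
    # longer than every year leaves the index undefined
    if (all(vapply(yrs, length, integer(1)) < max(rolling_window_sizes))) {
      abort("90-day rolling window longer than every water year",
            class = "eflowalt_input_error")
    }
  }
  roll_stat <- function(w, fn) {
    v <- vapply(yrs, function(x) {
      r <- .roll_mean(x, w)
      if (length(r)) fn(r) else NA_real_
    }, numeric(1))
    mean(v, na.rm = TRUE)
  }
  dl <- vapply(rolling_window_sizes, roll_stat, numeric(1), fn = min)
  dh <- vapply(rolling_window_sizes, roll_stat, numeric(1), fn = max)
  pulse_duration <- function(flag_fn) {
    mean(vapply(yrs, function(x) {
      d <- .run_lengths(flag_fn(x))
      if (length(d)) median(d) else 0
    }, numeric(1)))
  }
  dl18 <- mean(vapply(yrs, function(x) sum(x == 0) * 365 / length(x), numeric(1)))
  out <- c(
    setNames(dl, paste0("DL", 1:5)),
    DL16 = pulse_duration(function(x) x < thresholds$low),
    DL18 = dl18,
    setNames(dh, paste0("DH", 1:5)),
    DH15 = pulse_duration(function(x) x > thresholds$high)
  )
  tibble::as_tibble(as.list(out))
}

#' Low/high pulse thresholds for a screened record
#'
#' 25th and 75th percentiles of all daily flows in the screened record, the
#' standard convention for low/high pulse indices.
#'
#' @inheritParams magnitude_metrics
#' @param probs two probabilities (low, high).
#' @return list with elements `low` and `high`.
#' @export
pulse_thresholds <- function(series, probs = c(0.25, 0.75)) {
  qs <- quantile(series$discharge, probs, names = FALSE)
  list(low = qs[1], high = qs[2])
}

#' Frequency metrics (FL, FH families)
#'
#' FL1: mean annual count of distinct excursions (maximal runs of
#' consecutive days) below the low pulse threshold; FH1: analogous count
#' above the high threshold; FH6 and FH7: mean annual counts of events above
#' 3x and 7x the median daily flow. Counts are prorated to a 365-day year.
#'
#' @inheritParams duration_metrics
#' @return one-row tibble of metric values.
#' @export
frequency_metrics <- function(series, thresholds = pulse_thresholds(series)) {
  yrs <- .year_split(series)
  med <- median(series$discharge)
  count_events <- function(flag_fn) {
    mean(vapply(yrs, function(x) {
      length(.run_lengths(flag_fn(x))) * 365 / length(x)
    }, numeric(1)))
  }
  tibble::tibble(
    FL1 = count_events(function(x) x < thresholds$low),
    FH1 = count_events(function(x) x > thresholds$high),
    FH6 = count_events(function(x) x > 3 * med),
    FH7 = count_events(function(x) x > 7 * med)
  )
}

#' Timing metrics: Colwell's constancy (TA1) and predictability (TA2)
#'
#' Daily flows are cross-classified by calendar month (12 periods) and flow
#' state. Positive flows fall into `n_states` logarithmically spaced classes
#' between the record minimum and maximum positive flow; zero flows occupy a
#' dedicated state. With column (month) entropy H(X), row (state) entropy
#' H(Y) and joint entropy H(XY), constancy C = 1 - H(Y)/log s and
#' predictability P = 1 - (H(XY) - H(X))/log s, where s is the number of
#' defined states. Both lie in \[0, 1\] and equal 1 for constant flow.
#'
#' @inheritParams magnitude_metrics
#' @param n_states number of positive-flow classes (default 11).
#' @return one-row tibble with `TA1` and `TA2`.
#' @export
timing_metrics <- function(series, n_states = 11L) {
  q <- series$discharge
  mon <- as.integer(format(series$date, "%m"))
  pos <- q > 0
  has_zero <- any(!pos)
  state <- integer(length(q))
  if (any(pos)) {
    rng <- range(q[pos])
    if (rng[1] == rng[2]) {
      state[pos] <- 1L
    } else {
      brks <- exp(seq(log(rng[1]), log(rng[2]), length.out = n_states + 1L))
      s <- findInterval(q[pos], brks, rightmost.closed = TRUE, all.inside = TRUE)
      state[pos] <- s
    }
  }
  # zero flows form their own state above the positive classes
  state[!pos] <- n_states + 1L
  s_total <- n_states + as.integer(has_zero)
  tab <- table(month = mon, state = state)
  n <- sum(tab)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hx <- ent(rowSums(tab) / n)
  hy <- ent(colSums(tab) / n)
  hxy <- ent(as.numeric(tab) / n)
  logs <- log(s_total)
  if (logs <= 0) return(tibble::tibble(TA1 = 1, TA2 = 1))
  tibble::tibble(
    TA1 = clip01(1 - hy / logs),
    TA2 = clip01(1 - (hxy - hx) / logs)
  )
}

#' Rate-of-change metrics (RA family)
#'
#' Day-over-day differences are taken within each water year. RA1 is the
#' mean of positive differences (rise rate) and RA3 the mean magnitude of
#' negative differences (fall rate, stored as a positive number); both are 0
#' when no qualifying day exists. RA8 is the mean annual count of reversals
#' (sign changes in the sequence of non-zero differences), prorated to 365.
#'
#' @inheritParams magnitude_metrics
#' @return one-row tibble with `RA1`, `RA3`, `RA8`.
#' @export
rate_metrics <- function(series) {
  yrs <- .year_split(series)
  diffs <- lapply(yrs, diff)
  all_d <- unlist(diffs, use.names = FALSE)
  pos <- all_d[all_d > 0]
  neg <- all_d[all_d < 0]
  rev_count <- vapply(seq_along(diffs), function(i) {
    d <- diffs[[i]]
    s <- sign(d[d != 0])
    n_rev <- if (length(s) > 1L) sum(s[-1] != s[-length(s)]) else 0L
    n_rev * 365 / length(yrs[[i]])
  }, numeric(1))
  tibble::tibble(
    RA1 = if (length(pos)) mean(pos) else 0,
    RA3 = if (length(neg)) mean(abs(neg)) else 0,
    RA8 = mean(rev_count)
  )
}

#' Compute the full hydrologic metric vector for one gauge
#'
#' Unions the magnitude, duration, frequency, timing and rate families into
#' a single one-row tibble keyed by index code. The per-area indices MA41
#' and MH20 are returned as `NA` (with a message) when the series carries no
#' drainage area.
#'
#' @inheritParams magnitude_metrics
#' @param screen if `TRUE` (default) the series is passed through
#'   [screen_record()] first; set `FALSE` for already-screened input.
#' @param ... passed to [screen_record()].
#' @return one-row tibble with 41 metric columns plus `gauge_id` and
#'   `n_years` (complete water years used).
#' @export
compute_metric_vector <- function(series, screen = TRUE, ...) {
  scr <- if (screen) screen_record(series, ...) else series
  area <- flow_attr(scr, "drainage_area")
  mag <- if (is.na(area %||% NA_real_)) {
    # compute without the per-area pair rather than failing the whole vector
    tmp <- scr
    attr(tmp, "drainage_area") <- 1
    m <- magnitude_metrics(tmp)
    m$MA41 <- NA_real_; m$MH20 <- NA_real_
    m
  } else {
    magnitude_metrics(scr)
  }
  th <- pulse_thresholds(scr)
  out <- dplyr::bind_cols(
    tibble::tibble(
      gauge_id = flow_attr(scr, "gauge_id") %||% NA_character_,
      n_years = attr(scr, "n_complete_years") %||% length(unique(water_year(scr$date)))
    ),
    mag,
    duration_metrics(scr, th),
    frequency_metrics(scr, th),
    timing_metrics(scr),
    rate_metrics(scr)
  )
  out[, c("gauge_id", "n_years", metric_codes())]
}
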