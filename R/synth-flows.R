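# Synthetic daily flow regimes: class-specific seasonal sinusoid with
# multiplicative lognormal noise and Poisson storm pulses, plus disturbance
# operators (withdrawal, dam smoothing/release floor, urban spikes,
# seasonal rotation) that produce the non-reference condition.

#' Class-specific flow-regime parameters
#'
#' Deterministic parameter table for `n_classes` hydrologic classes:
#' specific runoff (flow per km2 of drainage area), seasonal amplitude and
#' phase, lognormal noise sd, storm-pulse rate and scale, and an
#' intermittency flag (the last class, when `n_classes >= 3`, has a dry
#'-season floor that produces genuine zero-flow days).
#'
#' @param n_classes number of classes.
#' @return tibble, one row per class.
#' @export
flow_class_params <- function(n_classes = 4L) {
  i <- seq_len(n_classes)
  tibble::tibble(
    hydro_class = sprintf("C%02d", i),
    specific_runoff = 0.04 + 0.02 * ((i - 1L) %% 3L),   # flow units per km2
    amplitude = seq(0.3, 0.8, length.out = n_classes),
    phase_day = round(seq(30, 330, length.out = n_classes)),
    noise_sd = 0.15 + 0.05 * ((i - 1L) %% 2L),
    storm_rate = 8 + 4 * ((i - 1L) %% 3L),              # pulses per year
    storm_scale = 2.5,
    recession = 0.35,                                   # day^-1 decay
    intermittent = if (n_classes >= 3L) i == n_classes else rep(FALSE, n_classes),
    dry_floor_frac = ifelse(if (n_classes >= 3L) i == n_classes else FALSE, 0.45, 0)
  )
}

#' Simulation switches for the reference-flow generator
#' @param noise,storms enable lognormal noise / storm pulses.
#' @param start first date of the record (start of a water year).
#' @return list of options.
#' @export
flow_sim_config <- function(noise = TRUE, storms = TRUE,
                            start = as.Date("2000-10-01")) {
  list(noise = noise, storms = storms, start = start)
}

#' Simulate a reference (least-disturbed) daily flow series
#'
#' The deterministic skeleton is `mu * (1 + A * sin(2*pi*(t - phase)/365))`
#' with `mu = specific_runoff * drainage_area`; multiplicative lognormal
#' noise and exponentially decaying Poisson storm pulses are added on top.
#' Intermittent classes subtract a dry-season floor and clip at zero, so
#' zero-flow days occur. Years are fixed at 365 days (no leap days).
#'
#' @param gauge one-row tibble (or list) with at least `gauge_id`,
#'   `hydro_class`, `drainage_area`.
#' @param n_years record length in water years (>= 15 to pass screening).
#' @param seed integer seed.
#' @param class_params parameter table from [flow_class_params()]; must
#'   contain the gauge's class.
#' @param config switches from [flow_sim_config()].
#' @return a [daily_flow_series()] of length `n_years * 365`.
#' @export
simulate_reference_flow <- function(gauge, n_years = 20L, seed = 1L,
                                    class_params = flow_class_params(),
                                    config = flow_sim_config()) {
  if (n_years < 1L) abort("n_years must be >= 1", class = "eflowalt_input_error")
  p <- class_params[class_params$hydro_class == gauge$hydro_class, ]
  if (nrow(p) != 1L) {
    abort(sprintf("unknown hydro_class '%s'", gauge$hydro_class),
          class = "eflowalt_input_error")
  }
  n_days <- n_years * 365L
  mu <- p$specific_runoff * gauge$drainage_area
  doy <- rep(seq_len(365L), n_years)
  base <- mu * (1 + p$amplitude * sin(2 * pi * (doy - p$phase_day) / 365))
  with_seed(seed, {
    q <- base
    if (isTRUE(config$noise)) {
      q <- q * exp(rnorm(n_days, 0, p$noise_sd))
    }
    if (isTRUE(config$storms)) {
      n_storm <- rpois(1L, p$storm_rate * n_years)
      if (n_storm > 0L) {
        t0 <- sample.int(n_days, n_storm, replace = TRUE)
        amp <- mu * p$storm_scale * stats::rexp(n_storm)
        pulse <- numeric(n_days)
        horizon <- 12L
        for (k in seq_len(n_storm)) {
          idx <- t0[k]:min(n_days, t0[k] + horizon)
          pulse[idx] <- pulse[idx] + amp[k] * exp(-p$recession * (idx - t0[k]))
        }
        q <- q + pulse
      }
    }
    if (isTRUE(p$intermittent)) q <- pmax(q - p$dry_floor_frac * mu, 0)
    daily_flow_series(
      date = seq_days_no_leap(config$start, n_days),
      discharge = pmax(q, 0),
      gauge_id = gauge$gauge_id %||% NA_character_,
      units = "cfs",
      drainage_area = gauge$drainage_area
    )
  })
}

#' Disturbance operator configuration
#' @param max_smooth_window longest dam moving-average window (days) at
#'   intensity 1.
#' @param release_quantile reference quantile used for the dam minimum
#'   -release floor.
#' @param spike_rate urban storm-spike rate (events/year) at flashiness 1.
#' @param spike_scale spike magnitude as a multiple of mean flow.
#' @return list of options.
#' @export
disturbance_config <- function(max_smooth_window = 31L, release_quantile = 0.2,
                               spike_rate = 25, spike_scale = 2.5) {
  list(max_smooth_window = max_smooth_window, release_quantile = release_quantile,
       spike_rate = spike_rate, spike_scale = spike_scale)
}

# centred moving average with edge shrinkage (window forced odd)
.smooth_ma <- function(x, w) {
  if (w <= 1L) return(x)
  if (w %% 2L == 0L) w <- w + 1L
  k <- rep(1 / w, w)
  s <- stats::filter(x, k, sides = 2)
  s <- as.numeric(s)
  # shrink the window at the edges instead of dropping to NA
  half <- (w - 1L) %/% 2L
  n <- length(x)
  for (i in which(is.na(s))) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    s[i] <- mean(x[lo:hi])
  }
  s
}

#' Impose a human-disturbance profile on a reference flow series
#'
#' Withdrawal scales all flows down by `1 - withdrawal_fraction`. Dam
#' storage blends the series toward a moving average (window grows with
#' intensity) and imposes a minimum-release floor, damping high-flow maxima
#' and raising low-flow minima. Urban flashiness adds short storm-coincident
#' spikes followed by fast recessions. A seasonal shift rotates each water
#' year circularly by `30 * seasonal_shift_months` days. A zero profile
#' returns the input unchanged; any negative flows produced are clipped to
#' zero and counted in the `n_clipped` attribute.
#'
#' @param reference a `daily_flow` series (reference condition).
#' @param profile one-row tibble/list with `dam_storage_intensity`,
#'   `withdrawal_fraction`, `urban_flashiness`, `seasonal_shift_months`.
#' @param seed integer seed (urban spikes are stochastic).
#' @param config [disturbance_config()] options.
#' @return a `daily_flow` series of the same length and dates.
#' @export
apply_disturbance <- function(reference, profile, seed = 1L,
                              config = disturbance_config()) {
  dam <- profile$dam_storage_intensity %||% 0
  wd <- profile$withdrawal_fraction %||% 0
  urb <- profile$urban_flashiness %||% 0
  shift <- profile$seasonal_shift_months %||% 0L
  stopifnot(dam >= 0, dam <= 1, wd >= 0, wd < 1, urb >= 0, urb <= 1,
            shift >= 0, shift <= 6)
  q <- reference$discharge
  if (dam == 0 && wd == 0 && urb == 0 && shift == 0) {
    return(reference)
  }
  wy <- water_year(reference$date)
  with_seed(seed, {
    if (shift > 0) {
      rot <- function(x, k) if (k %% length(x) == 0L) x else
        c(x[(k + 1L):length(x)], x[1L:k])
      q <- unlist(lapply(split(q, wy), rot, k = as.integer(30L * shift)),
                  use.names = FALSE)
    }
    if (dam > 0) {
      w <- 1L + round(dam * (config$max_smooth_window - 1L))
      sm <- .smooth_ma(q, w)
      q <- (1 - dam) * q + dam * sm
      floor_q <- dam * quantile(reference$discharge, config$release_quantile,
                                names = FALSE)
      q <- pmax(q, floor_q)
    }
    if (wd > 0) q <- q * (1 - wd)
    if (urb > 0) {
      n <- length(q)
      n_years <- length(unique(wy))
      n_spike <- rpois(1L, urb * config$spike_rate * n_years)
      if (n_spike > 0L) {
        t0 <- sample.int(n, n_spike, replace = TRUE)
        amp <- urb * config$spike_scale * mean(q) * stats::rexp(n_spike)
        for (k in seq_len(n_spike)) {
          idx <- t0[k]:min(n, t0[k] + 2L)
          q[idx] <- q[idx] + amp[k] * exp(-1.2 * (idx - t0[k]))
        }
      }
    }
    n_clipped <- sum(q < 0)
    q <- pmax(q, 0)
    out <- daily_flow_series(reference$date, q,
                             gauge_id = flow_attr(reference, "gauge_id"),
                             units = flow_attr(reference, "units"),
                             drainage_area = flow_attr(reference, "drainage_area"))
    attr(out, "n_clipped") <- n_clipped
    out
  })
}
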