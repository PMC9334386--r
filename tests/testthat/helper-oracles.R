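# Fixture builders and independent brute-force oracles used across tests.

# daily flow series with the given values repeated/recycled over n_years
make_series <- function(values, n_years = NULL, gauge_id = "T1",
                        drainage_area = 10) {
  if (!is.null(n_years)) {
    values <- rep_len(values, n_years * 365L)
  }
  n_years <- length(values) / 365L
  daily_flow_series(synthetic_dates(n_years), values, gauge_id = gauge_id,
                    drainage_area = drainage_area)
}

constant_series <- function(value = 5, n_years = 16) {
  make_series(rep(value, n_years * 365L))
}

random_series <- function(n_years, seed, allow_zero = FALSE) {
  withr::with_seed(seed, {
    q <- exp(rnorm(n_years * 365L, log(10), 0.8))
    if (allow_zero) q[runif(length(q)) < 0.05] <- 0
    make_series(q)
  })
}

# exhaustive rolling-window oracle: mean over water years of the annual
# min/max of w-day window means, scanning every window explicitly
oracle_roll_extreme <- function(series, w, fn) {
  by_year <- split(series$discharge, water_year(series$date))
  vals <- vapply(by_year, function(x) {
    n <- length(x)
    if (n < w) return(NA_real_)
    means <- vapply(w:n, function(i) mean(x[(i - w + 1L):i]), numeric(1))
    fn(means)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

# brute-force run-length scanner: per-year event counts (prorated to 365)
# and median event durations for a day-level predicate
oracle_run_scan <- function(series, pred) {
  by_year <- split(series$discharge, water_year(series$date))
  scan <- function(x) {
    flag <- pred(x)
    runs <- integer(0)
    cur <- 0L
    for (f in flag) {
      if (f) cur <- cur + 1L
      else if (cur > 0L) { runs <- c(runs, cur); cur <- 0L }
    }
    if (cur > 0L) runs <- c(runs, cur)
    runs
  }
  counts <- vapply(by_year, function(x) length(scan(x)) * 365 / length(x),
                   numeric(1))
  durations <- vapply(by_year, function(x) {
    r <- scan(x); if (length(r)) median(r) else 0
  }, numeric(1))
  list(count = mean(counts), duration = mean(durations))
}

# literal broken-stick oracle: b_j sums written out longhand
oracle_broken_stick <- function(eigenvalues) {
  p <- length(eigenvalues)
  prop <- eigenvalues / sum(eigenvalues)
  k <- 0L
  for (j in seq_len(p)) {
    b_j <- 0
    for (i in j:p) b_j <- b_j + 1 / i
    b_j <- b_j / p
    if (prop[j] > b_j) k <- j else break
  }
  k
}

# exact check-loss of a candidate quantile line
check_loss <- function(x, y, tau, b0, b1) {
  r <- y - b0 - b1 * x
  sum(ifelse(r >= 0, tau * r, (tau - 1) * r))
}

# exact linear quantile regression by pair enumeration: the optimum passes
# through two data points, so scanning all pairs finds the global minimum
oracle_rq_pairs <- function(x, y, tau) {
  n <- length(x)
  best <- c(NA, NA)
  best_loss <- Inf
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (x[i] == x[j]) next
      b1 <- (y[j] - y[i]) / (x[j] - x[i])
      b0 <- y[i] - b1 * x[i]
      l <- check_loss(x, y, tau, b0, b1)
      if (l < best_loss) { best_loss <- l; best <- c(b0, b1) }
    }
  }
  list(beta0 = best[1], beta1 = best[2], loss = best_loss)
}

# compact pipeline configuration for fast end-to-end runs
small_config <- function(seed = 11) {
  cfg <- default_config(seed = seed)
  cfg$network$n_gauges <- 60L
  cfg$network$n_reaches <- 80L
  cfg$flows$n_years <- 16L
  cfg$expected$ntree <- 120L
  cfg$models$ntree <- 120L
  cfg$ecology$min_n <- 5L
  cfg$ecology$n_boot <- 20L
  cfg
}

# small network + covariates + a monotone alteration response in the dam
# -storage intensity, for model-recovery tests
recovery_fixture <- function(n_gauges = 200, noise_sd = 0.05, seed = 5) {
  net <- generate_gauge_network(n_gauges, n_regions = 4, n_classes = 4,
                                reference_fraction = 0.4, seed = seed)
  cov <- generate_covariates(net, noise_sd = noise_sd, seed = seed + 1)
  g <- net$gauges
  truth <- pmin(pmax(0.9 * sqrt(g$dam_storage_intensity), 0), 1)
  training <- dplyr::bind_cols(
    g[, c("gauge_id", "is_reference", "region")],
    cov[match(g$gauge_id, cov$unit_id),
        setdiff(names(cov), c("unit_id", "unit_type"))])
  training$alteration <- truth
  list(network = net, training = training, truth = truth)
}
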