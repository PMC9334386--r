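# Metric engine: closed forms, brute-force oracles, invariances.

test_that("record screening keeps complete water years and fails short records", {
  s <- constant_series(5, 20)
  scr <- screen_record(s)
  expect_equal(attr(scr, "n_complete_years"), 20)
  expect_true(all(screen_report(scr)$kept))

  # one year with 31 missing days is dropped, leaving exactly 15 -> pass
  s16 <- constant_series(5, 16)
  wy <- water_year(s16$date)
  drop_year <- unique(wy)[3]
  idx <- which(wy == drop_year)[1:31]
  s16$discharge[idx] <- NA
  scr16 <- screen_record(s16)
  expect_equal(attr(scr16, "n_complete_years"), 15)
  rep16 <- screen_report(scr16)
  expect_false(rep16$kept[rep16$water_year == drop_year])
  expect_equal(rep16$n_missing[rep16$water_year == drop_year], 31)

  # a year with exactly 30 missing days is still complete
  s30 <- constant_series(5, 16)
  s30$discharge[which(water_year(s30$date) == drop_year)[1:30]] <- NA
  expect_equal(attr(screen_record(s30), "n_complete_years"), 16)

  expect_error(screen_record(constant_series(5, 14)),
               class = "eflowalt_screening_error")
})

test_that("constant flow gives the closed-form metric limits", {
  mv <- compute_metric_vector(constant_series(5, 16))
  expect_equal(mv$MA1, 5)
  expect_equal(mv$MA2, 5)
  expect_equal(mv$MA3, 0)
  expect_equal(mv$ML19, 100)
  expect_equal(mv$MH20, 0.5)  # max 5 / area 10
  expect_equal(mv$DL1, 5)
  expect_equal(mv$DH1, 5)
  expect_equal(mv$DL18, 0)
  expect_equal(mv$FL1, 0)
  expect_equal(mv$FH1, 0)
  expect_equal(mv$FH6, 0)
  expect_equal(mv$FH7, 0)
  expect_equal(mv$TA1, 1)
  expect_equal(mv$TA2, 1)
  expect_equal(mv$RA1, 0)
  expect_equal(mv$RA3, 0)
  expect_equal(mv$RA8, 0)
  expect_true(all(as.numeric(mv[, paste0("MA", 12:23)]) == 5))
})

test_that("alternating flows match direct sd/mean arithmetic", {
  s <- make_series(rep(c(2, 4), length.out = 16 * 365))
  mv <- compute_metric_vector(s)
  expect_equal(mv$MA1, 3)
  expect_equal(mv$MA3, 100 * sd(s$discharge) / mean(s$discharge))
})

test_that("single zero-flow day is counted and floors the 1-day minimum", {
  q <- rep(10, 16 * 365)
  wy_days <- which(water_year(synthetic_dates(16)) == 2002)
  q[wy_days[100]] <- 0
  mv <- compute_metric_vector(make_series(q))
  expect_equal(mv$DL1, 0 / 16 + 10 * 15 / 16)  # one year min 0, rest 10
  expect_equal(mv$DL18, 1 / 16)
})

test_that("rolling-window indices equal the exhaustive window oracle", {
  for (seed in 1:10) {
    s <- random_series(n_years = sample(2:3, 1), seed = seed)
    scr <- screen_record(s, min_years = 1)
    dm <- duration_metrics(scr)
    for (i in seq_along(c(1, 3, 7, 30, 90))) {
      w <- c(1, 3, 7, 30, 90)[i]
      expect_equal(dm[[paste0("DL", i)]], oracle_roll_extreme(scr, w, min),
                   tolerance = 1e-12)
      expect_equal(dm[[paste0("DH", i)]], oracle_roll_extreme(scr, w, max),
                   tolerance = 1e-12)
    }
  }
})

test_that("pulse counts and durations equal the brute-force run scanner", {
  for (seed in 11:16) {
    s <- random_series(n_years = 3, seed = seed, allow_zero = TRUE)
    scr <- screen_record(s, min_years = 1)
    th <- pulse_thresholds(scr)
    med <- median(scr$discharge)
    fm <- frequency_metrics(scr, th)
    dm <- duration_metrics(scr, th)
    lo <- oracle_run_scan(scr, function(x) x < th$low)
    hi <- oracle_run_scan(scr, function(x) x > th$high)
    expect_equal(fm$FL1, lo$count)
    expect_equal(fm$FH1, hi$count)
    expect_equal(fm$FH6, oracle_run_scan(scr, function(x) x > 3 * med)$count)
    expect_equal(fm$FH7, oracle_run_scan(scr, function(x) x > 7 * med)$count)
    expect_equal(dm$DL16, lo$duration)
    expect_equal(dm$DH15, hi$duration)
  }
})

test_that("hand-built event runs are counted as maximal runs", {
  # one year: baseline 1, two separated 5-day excursions to 10 (> 3x median)
  q <- rep(1, 365)
  q[50:54] <- 10
  q[200:204] <- 10
  s <- make_series(rep(q, 2))
  scr <- screen_record(s, min_years = 1)
  fm <- frequency_metrics(scr)
  expect_equal(fm$FH6, 2)

  # 65 contiguous high days form a single event
  q2 <- c(rep(1, 300), rep(100, 65))
  s2 <- make_series(rep(q2, 2))
  fm2 <- frequency_metrics(screen_record(s2, min_years = 1))
  expect_equal(fm2$FH1, 1)
})

test_that("Colwell timing metrics behave at the entropy limits", {
  # exact 12-month cycle repeated identically across years: perfectly
  # predictable (TA2 = 1) but not constant (TA1 < 1)
  month_levels <- rep(c(1, 1, 2, 4, 8, 16, 16, 8, 4, 2, 1, 1), c(31, 30, 31, 31, 28, 31, 30, 31, 30, 31, 30, 31))
  s <- make_series(rep(month_levels, 16))
  tm <- timing_metrics(screen_record(s))
  expect_equal(tm$TA2, 1, tolerance = 1e-10)
  expect_lt(tm$TA1, 1)

  # uniform states independent of month: TA1 ~ TA2 ~ 1 - log(s_occ)/log(s)
  set.seed(99)
  states <- sample(c(1, 2.2, 5, 11, 24), 16 * 365, replace = TRUE)
  tu <- timing_metrics(screen_record(make_series(states)))
  expect_equal(tu$TA1, tu$TA2, tolerance = 0.05)
  expect_equal(tu$TA1, 1 - log(5) / log(11), tolerance = 0.08)
})

test_that("rate metrics match direct difference scans", {
  # strictly increasing by 1 within each year
  s <- make_series(rep(seq_len(365), 16) + 10)
  rm1 <- rate_metrics(screen_record(s))
  expect_equal(rm1$RA1, 1)
  expect_equal(rm1$RA8, 0)

  # sawtooth +2/-2: every difference is a reversal of the previous one
  saw <- rep(c(10, 12), length.out = 365)
  rm2 <- rate_metrics(screen_record(make_series(rep(saw, 16))))
  expect_equal(rm2$RA1, 2)
  expect_equal(rm2$RA3, 2)
  expect_equal(rm2$RA8, 363)  # 364 diffs -> 363 sign alternations
})

test_that("scaling flows by k scales magnitudes and leaves ratios and counts unchanged", {
  s <- random_series(3, seed = 21)
  k <- 3.7
  sk <- make_series(s$discharge * k)
  a <- compute_metric_vector(s, min_years = 1)
  b <- compute_metric_vector(sk, min_years = 1)
  for (m in c("MA1", "MA2", "DL1", "DL3", "DH1", "DH5", "RA1", "RA3")) {
    expect_equal(b[[m]], k * a[[m]], tolerance = 1e-10)
  }
  for (m in c("MA3", "ML17", "ML19", "TA1", "TA2", "FL1", "FH1", "FH6",
              "FH7", "DL18", "RA8")) {
    expect_equal(b[[m]], a[[m]], tolerance = 1e-10)
  }
})

test_that("monthly means are invariant to permuting days within months", {
  s <- random_series(2, seed = 31)
  mon <- format(s$date, "%Y-%m")
  q2 <- s$discharge
  for (m in unique(mon)) {
    i <- which(mon == m)
    q2[i] <- withr::with_seed(7, sample(s$discharge[i]))
  }
  s2 <- make_series(q2)
  a <- magnitude_metrics(screen_record(s, min_years = 1))
  b <- magnitude_metrics(screen_record(s2, min_years = 1))
  expect_equal(as.numeric(b[, paste0("MA", 12:23)]),
               as.numeric(a[, paste0("MA", 12:23)]))
})

test_that("metric vector is deterministic and respects type invariants", {
  net <- generate_gauge_network(4, seed = 3)
  s <- simulate_reference_flow(net$gauges[1, ], n_years = 20, seed = 4)
  v1 <- compute_metric_vector(s)
  v2 <- compute_metric_vector(s)
  expect_identical(v1, v2)
  vals <- as.numeric(v1[, metric_codes()])
  expect_true(all(is.finite(vals)))
  expect_true(v1$TA1 >= 0 && v1$TA1 <= 1)
  expect_true(v1$TA2 >= 0 && v1$TA2 <= 1)
  expect_true(v1$DL18 >= 0)
  # longer-window minima are at least the shorter-window minima (and
  # conversely for maxima)
  expect_true(v1$DL1 <= v1$DL2 + 1e-12 && v1$DL2 <= v1$DL3 + 1e-12 &&
                v1$DL3 <= v1$DL4 + 1e-12 && v1$DL4 <= v1$DL5 + 1e-12)
  expect_true(v1$DH1 >= v1$DH2 - 1e-12 && v1$DH2 >= v1$DH3 - 1e-12 &&
                v1$DH3 >= v1$DH4 - 1e-12 && v1$DH4 >= v1$DH5 - 1e-12)
})

test_that("per-area metrics demand a drainage area", {
  s <- daily_flow_series(synthetic_dates(16), rep(5, 16 * 365))
  expect_error(magnitude_metrics(screen_record(s)),
               class = "eflowalt_input_error")
  mv <- compute_metric_vector(s)  # degrades to NA rather than failing
  expect_true(is.na(mv$MA41) && is.na(mv$MH20))
  expect_equal(mv$MA1, 5)
})
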