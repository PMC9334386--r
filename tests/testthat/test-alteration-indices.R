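# Alteration calculus, seasonality, broken stick, PCA/HAI, regional scaling.

test_that("capped proportional alteration follows the (O-E)/E rules", {
  expect_equal(compute_alteration(5, 5), 0)
  expect_equal(compute_alteration(5, 1), 1)     # ratio 4 capped at 1
  expect_equal(compute_alteration(0.5, 1), 0.5)
  expect_equal(compute_alteration(2, 1), 1)     # ratio exactly 1 stays 1
  expect_equal(compute_alteration(0, 0), 0)     # E = 0, O = 0 convention
  expect_equal(compute_alteration(3, 0), 1)     # E = 0, O > 0 convention
  # reference gauges short-circuit to zero whatever the values
  expect_equal(compute_alteration(5, 1, is_reference = TRUE), 0)

  # enumerated grid: always in [0, 1] and symmetric deviations agree
  grid <- expand.grid(o = c(0, 0.1, 0.5, 1, 2, 10), e = c(0, 0.5, 1, 3))
  a <- compute_alteration(grid$o, grid$e)
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(compute_alteration(1.2, 1), compute_alteration(0.8, 1))
})

test_that("interval (class-envelope) alteration measures distance to the nearest bound", {
  expect_equal(compute_alteration(5, lower = 4, upper = 6), 0)
  expect_equal(compute_alteration(4, lower = 4, upper = 6), 0)  # boundary inside
  expect_equal(compute_alteration(3, lower = 4, upper = 6), 0.25)
  expect_equal(compute_alteration(9, lower = 4, upper = 6), 0.5)
  expect_equal(compute_alteration(20, lower = 4, upper = 6), 1)  # capped
  expect_equal(compute_alteration(1, lower = 0, upper = 0), 1)   # zero bound, O > 0
})

test_that("seasonality sums monthly deviations, with signed cancellation only in literal mode", {
  e <- rep(2, 12)
  expect_equal(compute_seasonality(e, e), 0)
  expect_equal(compute_seasonality(e, e, signed = TRUE), 0)

  o <- e; o[1] <- 4  # January doubled
  expect_equal(compute_seasonality(o, e), 1)

  o2 <- e; o2[1] <- 4; o2[2] <- 0  # opposite shifts cancel when signed
  expect_equal(compute_seasonality(o2, e, signed = TRUE), 0)
  expect_equal(compute_seasonality(o2, e), 2)

  expect_error(compute_seasonality(1:6, 1:6), class = "eflowalt_input_error")
})

test_that("broken stick matches hand computation and the literal oracle", {
  expect_equal(broken_stick(c(0.6, 0.2, 0.1, 0.06, 0.04)), 1)
  # proportions exactly at the broken-stick expectation are not significant
  p <- 4
  b <- rev(cumsum(1 / rev(seq_len(p)))) / p
  expect_equal(broken_stick(sort(b, decreasing = TRUE)), 0)
  expect_equal(broken_stick(c(1)), 0)  # single component can never exceed b1 = 1
  expect_warning(k0 <- broken_stick(c(0, 0, 0)))
  expect_equal(k0, 0L)
  expect_error(broken_stick(c(0.2, 0.5)), class = "eflowalt_input_error")

  for (seed in 1:20) {
    ev <- withr::with_seed(seed, sort(rexp(sample(2:50, 1)), decreasing = TRUE))
    expect_equal(broken_stick(ev), oracle_broken_stick(ev))
  }
})

test_that("reference PCA captures shared variance and fixes signs deterministically", {
  withr::with_seed(11, {
    n <- 60
    shared <- rnorm(n)
    metrics <- tibble::tibble(
      gauge_id = sprintf("G%03d", 1:n),
      MA1 = 10 + 3 * shared,
      MA2 = 8 + 2.9 * shared + rnorm(n, 0, 0.01),
      MA3 = runif(n, 10, 30),
      TA1 = runif(n, 0.2, 0.9)
    )
  })
  gauges <- tibble::tibble(gauge_id = metrics$gauge_id,
                           is_reference = rep(c(TRUE, FALSE), 30),
                           hydro_class = rep(c("C01", "C02"), each = 30))
  pca <- fit_reference_pca(metrics, gauges)
  expect_equal(pca$k, oracle_broken_stick(pca$eigenvalues))
  expect_gt(pca$eigenvalues[1] / sum(pca$eigenvalues), 0.3)
  # PC1 loads the two correlated metrics together
  l1 <- pca$rotation[, 1]
  expect_gt(abs(l1[["MA1"]]), 0.4)
  expect_gt(abs(l1[["MA2"]]), 0.4)
  expect_equal(sign(l1[["MA1"]]), sign(l1[["MA2"]]))

  pca2 <- fit_reference_pca(metrics, gauges)
  expect_identical(pca$rotation, pca2$rotation)

  # envelopes lie inside the reference score range
  for (cl in unique(gauges$hydro_class)) {
    sc <- pca$scores$PC1[pca$scores$is_reference &
                           pca$scores$hydro_class == cl]
    env <- pca$envelopes[pca$envelopes$hydro_class == cl &
                           pca$envelopes$component == 1, ]
    expect_gte(env$a, min(sc))
    expect_lte(env$b, max(sc))
  }

  metrics$MA3 <- 5  # constant column is dropped with a warning
  expect_warning(pca3 <- fit_reference_pca(metrics, gauges), "constant")
  expect_false("MA3" %in% pca3$metrics)
})

test_that("HAI is the eigenvalue-weighted excursion outside the envelopes", {
  expect_equal(compute_hai(c(0, 0.5), c(-1, -1), c(1, 1), c(2, 1.2)), 0)
  expect_equal(compute_hai(1.5, -1, 1, 2), 1.0)
  expect_equal(compute_hai(c(0, -1.25), c(-0.5, -1), c(0.5, 1), c(2, 1.2)),
               0.25 * 1.2)
  # weakly increasing in the excursion size
  h1 <- compute_hai(1.2, -1, 1, 2)
  h2 <- compute_hai(1.4, -1, 1, 2)
  expect_gt(h2, h1)
})

test_that("regional min-max scaling is a rank-preserving [0,1] map per region", {
  expect_equal(minmax_scale_by_region(c(2, 4, 6), rep("A", 3)),
               c(0, 0.5, 1))
  x <- c(2, 4, 6, 10, 20)
  r <- c("A", "A", "A", "B", "B")
  s <- minmax_scale_by_region(x, r)
  expect_equal(range(s[r == "A"]), c(0, 1))
  expect_equal(range(s[r == "B"]), c(0, 1))
  # adding a new maximum rescales others downward but preserves ranks
  x2 <- c(x[1:3], 100)
  s2 <- minmax_scale_by_region(x2, rep("A", 4))
  expect_true(all(diff(order(s2[1:3])) == diff(order(x[1:3]))))
  expect_true(all(s2[1:3] <= minmax_scale_by_region(x[1:3], rep("A", 3)) + 1e-12))
  expect_warning(z <- minmax_scale_by_region(c(3, 3), c("A", "A")))
  expect_equal(z, c(0, 0))
})

test_that("expected conditions recover a cloned gauge and degenerate envelopes", {
  # zero-noise synthetic: a non-reference gauge with covariates identical to
  # a reference gauge should get an expected value close to that gauge's
  net <- generate_gauge_network(40, n_classes = 2, reference_fraction = 0.5,
                                seed = 6)
  g <- net$gauges
  clone_src <- which(g$is_reference)[1]
  clone_dst <- which(!g$is_reference)[1]
  g$drainage_area[clone_dst] <- g$drainage_area[clone_src]
  g$hydro_class[clone_dst] <- g$hydro_class[clone_src]
  net$gauges <- g
  cov <- generate_covariates(net, noise_sd = 0, seed = 1)

  metrics <- purrr::map_dfr(seq_len(nrow(g)), function(i) {
    s <- simulate_reference_flow(g[i, ], n_years = 15, seed = 100 + i,
                                 class_params = flow_class_params(2),
                                 config = flow_sim_config(noise = FALSE,
                                                          storms = FALSE))
    compute_metric_vector(s)
  })
  exp_cond <- estimate_reference_conditions(metrics, g, cov,
                                            ntree = 200, seed = 2)
  e_ma1 <- exp_cond[exp_cond$metric == "MA1" &
                      exp_cond$gauge_id == g$gauge_id[clone_dst], ]
  truth <- metrics$MA1[clone_src]
  expect_equal(e_ma1$e_point, truth, tolerance = 0.25)
  expect_equal(e_ma1$provenance, "model")

  # unreliable metrics get the class envelope; a reference gauge's own
  # expected value sits within its class spread
  ta <- exp_cond[exp_cond$metric == "TA1", ]
  expect_true(all(ta$provenance == "class-envelope"))
  expect_true(all(ta$e_lower <= ta$e_upper))
  ref_row <- exp_cond[exp_cond$metric == "MA1" &
                        exp_cond$gauge_id %in% g$gauge_id[g$is_reference], ]
  cls_rng <- range(metrics$MA1[g$is_reference])
  expect_true(all(ref_row$e_point >= cls_rng[1] - 1e-9 &
                    ref_row$e_point <= cls_rng[2] + 1e-9))

  expect_error(
    estimate_reference_conditions(metrics,
                                  dplyr::mutate(g, is_reference = FALSE),
                                  cov),
    class = "eflowalt_reference_error")
})

test_that("alteration table zeroes reference gauges and stays in [0,1]", {
  metrics <- tibble::tibble(gauge_id = c("A", "B", "C"),
                            MA1 = c(10, 5, 30), MA2 = c(8, 4, 20))
  expected <- tidyr::expand_grid(gauge_id = c("A", "B", "C"),
                                 metric = c("MA1", "MA2"))
  expected$e_point <- 10
  expected$e_lower <- NA_real_
  expected$e_upper <- NA_real_
  expected$provenance <- "model"
  gauges <- tibble::tibble(gauge_id = c("A", "B", "C"),
                           is_reference = c(TRUE, FALSE, FALSE))
  at <- alteration_table(metrics, expected, gauges)
  expect_true(all(at$alteration >= 0 & at$alteration <= 1))
  expect_true(all(at$alteration[at$gauge_id == "A"] == 0))
  expect_equal(at$alteration[at$gauge_id == "B" & at$metric == "MA1"], 0.5)
  expect_equal(at$alteration[at$gauge_id == "C" & at$metric == "MA1"], 1)
})
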