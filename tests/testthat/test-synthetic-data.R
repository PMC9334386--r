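# Generator contracts: determinism, partitions, disturbance operators,
# covariate linkage, wedge geometry.

test_that("network generation honours counts, fractions and determinism", {
  net <- generate_gauge_network(10, reference_fraction = 0.5, seed = 1)
  expect_equal(sum(net$gauges$is_reference), 5)
  expect_equal(sum(!net$gauges$is_reference), 5)

  net2 <- generate_gauge_network(10, reference_fraction = 0.5, seed = 1)
  expect_identical(net$gauges, net2$gauges)
  expect_identical(net$reaches, net2$reaches)

  big <- generate_gauge_network(200, n_regions = 4, seed = 7)
  expect_setequal(unique(big$gauges$region), big$regions)
  expect_true(all(table(big$gauges$region) > 0))

  expect_error(generate_gauge_network(1), class = "eflowalt_input_error")
  expect_error(generate_gauge_network(10, reference_fraction = 1),
               class = "eflowalt_input_error")
})

test_that("reference gauges carry zero disturbance, positive areas, one region and class", {
  net <- generate_gauge_network(50, seed = 2)
  g <- net$gauges
  expect_true(all(g$drainage_area > 0))
  expect_false(any(duplicated(g$gauge_id)))
  ref <- g[g$is_reference, ]
  expect_true(all(ref$dam_storage_intensity == 0))
  expect_true(all(ref$withdrawal_fraction == 0))
  expect_true(all(ref$urban_flashiness == 0))
  expect_true(all(ref$seasonal_shift_months == 0))
  expect_true(all(g$region %in% net$regions))
  expect_true(all(g$hydro_class %in% net$classes))
})

test_that("noise-free reference flow is the pure seasonal sinusoid", {
  net <- generate_gauge_network(5, seed = 1)
  g <- net$gauges[1, ]
  s <- simulate_reference_flow(g, n_years = 16, seed = 1,
                               config = flow_sim_config(noise = FALSE,
                                                        storms = FALSE))
  p <- flow_class_params(4)
  p <- p[p$hydro_class == g$hydro_class, ]
  mu <- p$specific_runoff * g$drainage_area
  # the sinusoid sums to zero over each full 365-day cycle
  expect_equal(compute_metric_vector(s)$MA1, mu, tolerance = 1e-12)
  expect_equal(nrow(s), 16 * 365)

  s2 <- simulate_reference_flow(g, n_years = 16, seed = 1,
                                config = flow_sim_config(noise = FALSE,
                                                         storms = FALSE))
  expect_identical(s$discharge, s2$discharge)
  expect_error(simulate_reference_flow(g, n_years = 0),
               class = "eflowalt_input_error")
})

test_that("stochastic flow simulation is seed-deterministic", {
  net <- generate_gauge_network(5, seed = 1)
  g <- net$gauges[2, ]
  a <- simulate_reference_flow(g, n_years = 16, seed = 42)
  b <- simulate_reference_flow(g, n_years = 16, seed = 42)
  expect_identical(a, b)
  c <- simulate_reference_flow(g, n_years = 16, seed = 43)
  expect_false(identical(a$discharge, c$discharge))
})

test_that("the intermittent class produces genuine zero-flow days", {
  net <- generate_gauge_network(40, n_classes = 4, seed = 9)
  cls <- flow_class_params(4)
  int_class <- cls$hydro_class[cls$intermittent]
  g <- net$gauges[net$gauges$hydro_class == int_class, ][1, ]
  s <- simulate_reference_flow(g, n_years = 16, seed = 5)
  mv <- compute_metric_vector(s)
  expect_gt(mv$DL18, 0)
})

test_that("disturbance operators act as designed on the flow metrics", {
  net <- generate_gauge_network(5, seed = 1)
  g <- net$gauges[1, ]
  s <- simulate_reference_flow(g, n_years = 16, seed = 2)
  zero <- list(dam_storage_intensity = 0, withdrawal_fraction = 0,
               urban_flashiness = 0, seasonal_shift_months = 0L)

  expect_identical(apply_disturbance(s, zero), s)

  wd <- modifyList(zero, list(withdrawal_fraction = 0.5))
  expect_equal(compute_metric_vector(apply_disturbance(s, wd, seed = 3))$MA1,
               0.5 * compute_metric_vector(s)$MA1, tolerance = 1e-10)

  dam <- modifyList(zero, list(dam_storage_intensity = 0.8))
  m_ref <- compute_metric_vector(s)
  m_dam <- compute_metric_vector(apply_disturbance(s, dam, seed = 3))
  expect_lt(m_dam$MA3, m_ref$MA3)
  expect_lte(m_dam$DH1, m_ref$DH1)

  # monotonicity: more withdrawal means strictly less mean flow
  wd2 <- modifyList(zero, list(withdrawal_fraction = 0.7))
  expect_lt(compute_metric_vector(apply_disturbance(s, wd2, seed = 3))$MA1,
            compute_metric_vector(apply_disturbance(s, wd, seed = 3))$MA1)

  # urban flashiness raises rise rate and high-pulse frequency
  urb <- modifyList(zero, list(urban_flashiness = 0.8))
  m_urb <- compute_metric_vector(apply_disturbance(s, urb, seed = 3))
  expect_gt(m_urb$RA1, m_ref$RA1)
  expect_gte(m_urb$FH1, m_ref$FH1)
})

test_that("covariates are monotone transforms of true disturbance", {
  net <- generate_gauge_network(80, seed = 4)
  cov0 <- generate_covariates(net, noise_sd = 0, seed = 1)
  g <- net$gauges
  co <- cov0[match(g$gauge_id, cov0$unit_id), ]
  nonref <- !g$is_reference
  expect_equal(cor(co$dam_01[nonref], g$dam_storage_intensity[nonref],
                   method = "spearman"), 1)
  expect_equal(cor(co$urb_02[nonref], g$urban_flashiness[nonref],
                   method = "spearman"), 1)
  # reference gauges sit at the zero-disturbance baseline
  expect_true(all(co$dam_01[g$is_reference] == 0))
  expect_true(all(co$hdi_01[g$is_reference] == 0))
  # determinism and shape
  cov0b <- generate_covariates(net, noise_sd = 0, seed = 1)
  expect_identical(cov0, cov0b)
  expect_setequal(setdiff(names(cov0), c("unit_id", "unit_type")),
                  covariate_groups()$covariate)
  expect_equal(nrow(cov0), nrow(g) + nrow(net$reaches))
})

test_that("wedge fish responses respect their bounds and degenerate cases", {
  loc <- tibble::tibble(location_id = 1:200, region = "R01", huc4 = "0101",
                        ha = rep(0, 200))
  fish0 <- simulate_fish_responses(loc, true_threshold = 0.4, max_loss = 5,
                                   seed = 1)
  expect_true(all(fish0$richness_residual <= 0))
  expect_true(all(wedge_upper_bound(loc$ha, 0.4, 5) == 0))

  loc$ha <- seq(0, 1, length.out = 200)
  fish_nl <- simulate_fish_responses(loc, true_threshold = 0.4, max_loss = 0,
                                     seed = 1)
  expect_true(all(wedge_upper_bound(loc$ha, 0.4, 0) == 0))
  expect_true(all(fish_nl$richness_residual <= 0))

  fish <- simulate_fish_responses(loc, true_threshold = 0.4, max_loss = 5,
                                  seed = 2)
  ub <- wedge_upper_bound(loc$ha, 0.4, 5)
  expect_true(all(fish$richness_residual <= ub + 1e-12))
  expect_true(all(fish$richness_residual >= ub - 1 - 1e-12))

  expect_error(simulate_fish_responses(loc, true_threshold = 1.2),
               class = "eflowalt_input_error")
  expect_error(simulate_fish_responses(dplyr::select(loc, -"ha")),
               class = "eflowalt_input_error")
})

test_that("95th-quantile fit of the default wedge recovers the tipping point", {
  withr::with_seed(42, {
    loc <- tibble::tibble(location_id = 1:500, region = "R01", huc4 = "0101",
                          ha = runif(500))
  })
  fish <- simulate_fish_responses(loc, true_threshold = 0.4, max_loss = 5,
                                  seed = 7)
  fits <- fit_quantile_models(fish, metrics = "ha", taus = 0.95,
                              n_boot = 30, seed = 3)
  th <- derive_thresholds(fits)
  expect_lt(abs(th$threshold - 0.4), 0.1)
})
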