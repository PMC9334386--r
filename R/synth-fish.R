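# Wedge-shaped fish richness responses with a known tipping point.

#' Simulate fish richness residuals with a wedge response to alteration
#'
#' Each location's richness residual (observed minus expected native
#' richness) is drawn uniformly between an upper wedge bound
#' `U(HA)` and `U(HA) - wedge_width`. The upper bound is 0 for
#' `HA <= true_threshold` and declines linearly to `-max_loss` at `HA = 1`,
#' so the 95th-percentile quantile regression of residual on alteration
#' crosses zero near `true_threshold`. Uniform (not Gaussian) noise keeps
#' the fitted quantiles analytically predictable. The default band width of
#' one species keeps the upper envelope identifiable by a single linear
#' quantile fit: a much wider scatter band flattens the fitted line against
#' the flat pre-threshold limb and biases its zero crossing low.
#'
#' @param locations data frame with one row per survey location; must
#'   contain an alteration column `ha` in \[0,1\]; columns `location_id`,
#'   `region`, `huc4` and any per-metric alteration columns are carried
#'   through.
#' @param true_threshold alteration value of the tipping point (0 < T < 1).
#' @param max_loss species lost at full alteration (>= 0).
#' @param wedge_width vertical spread of the scatter band below the upper
#'   bound, in species units (default 1).
#' @param seed integer seed.
#' @return the input tibble plus `richness_residual`.
#' @export
simulate_fish_responses <- function(locations, true_threshold = 0.4,
                                    max_loss = 5, wedge_width = NULL,
                                    seed = 1L) {
  wedge_width <- wedge_width %||% 1
  if (!"ha" %in% names(locations)) {
    abort("`locations` must have an alteration column `ha`",
          class = "eflowalt_input_error")
  }
  ha <- locations$ha
  if (any(ha < 0 | ha > 1, na.rm = TRUE)) {
    abort("alteration values must lie in [0, 1]", class = "eflowalt_input_error")
  }
  if (true_threshold <= 0 || true_threshold >= 1) {
    abort("true_threshold must lie strictly between 0 and 1",
          class = "eflowalt_input_error")
  }
  if (max_loss < 0) abort("max_loss must be >= 0", class = "eflowalt_input_error")
  upper <- wedge_upper_bound(ha, true_threshold, max_loss)
  with_seed(seed, {
    res <- upper - wedge_width * runif(length(ha))
    out <- tibble::as_tibble(locations)
    out$richness_residual <- res
    out
  })
}

#' Upper wedge bound of the synthetic fish response
#'
#' @param ha alteration values in \[0,1\].
#' @param true_threshold tipping point.
#' @param max_loss species lost at `ha = 1`.
#' @return numeric vector: 0 below the threshold, declining linearly to
#'   `-max_loss` at `ha = 1`.
#' @export
wedge_upper_bound <- function(ha, true_threshold, max_loss) {
  ifelse(ha <= true_threshold, 0,
         -max_loss * (ha - true_threshold) / (1 - true_threshold))
}
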