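# Flow-ecology: wedge quantile regressions of fish-richness residuals on
# hydrologic alteration, tipping points where the fitted quantile crosses
# zero, binary threshold exceedance and the probability of fish
# biodiversity loss.

#' Fit linear quantile regressions of richness residuals on alteration
#'
#' For each HUC-4 subregion, metric (alteration column) and quantile tau, a
#' linear quantile regression `residual ~ alteration` is fit with
#' `quantreg::rq`. Subregion/metric combinations with fewer than `min_n`
#' observations or with constant alteration are skipped (recorded in the
#' `skipped` attribute). Slope standard errors come from a paired bootstrap
#' by default. The cumulative HAI is never fitted even when present.
#'
#' @param observations tibble with `region`, `huc4`, `richness_residual`
#'   and one or more alteration columns.
#' @param metrics names of alteration columns to fit (default: `"ha"` if
#'   present plus any registered metric codes; `"HAI"` always excluded).
#' @param taus quantiles to fit.
#' @param min_n minimum observations per subregion x metric.
#' @param se_method `"boot"` (paired bootstrap) or `"nid"` (sandwich).
#' @param n_boot bootstrap replicates for `se_method = "boot"`.
#' @param seed integer seed (bootstrap resampling).
#' @return tibble of class `quantile_fits`: `metric`, `subregion`,
#'   `region`, `tau`, `beta0`, `beta1`, `slope_se`, `n`, `provenance`,
#'   `se_method`; skipped combinations in `attr(, "skipped")`.
#' @export
fit_quantile_models <- function(observations, metrics = NULL,
                                taus = c(0.5, 0.75, 0.95), min_n = 20L,
                                se_method = c("boot", "nid"), n_boot = 100L,
                                seed = 1L) {
  se_method <- match.arg(se_method)
  metrics <- metrics %||%
    intersect(c("ha", metric_codes()), names(observations))
  metrics <- setdiff(metrics, c("HAI", "hai"))
  if (length(metrics) == 0L) {
    abort("no alteration columns to fit", class = "eflowalt_input_error")
  }
  combos <- tidyr::expand_grid(huc4 = unique(observations$huc4),
                               metric = metrics)
  seeds <- derive_seeds(seed, nrow(combos))
  skipped <- list()
  rows <- purrr::pmap(list(combos$huc4, combos$metric, seeds),
    function(h, m, s) {
      sub <- observations[observations$huc4 == h, , drop = FALSE]
      x <- sub[[m]]; y <- sub$richness_residual
      ok <- is.finite(x) & is.finite(y)
      x <- x[ok]; y <- y[ok]
      if (length(x) < min_n) {
        skipped[[length(skipped) + 1L]] <<- tibble::tibble(
          huc4 = h, metric = m, reason = sprintf("n = %d < %d", length(x), min_n))
        return(NULL)
      }
      if (diff(range(x)) == 0) {
        skipped[[length(skipped) + 1L]] <<- tibble::tibble(
          huc4 = h, metric = m, reason = "constant alteration")
        return(NULL)
      }
      purrr::map_dfr(taus, function(tt) {
        cf <- rq_line(x, y, tt)
        se <- rq_slope_se(x, y, tt, method = se_method, n_boot = n_boot,
                          seed = s)
        tibble::tibble(
          metric = m, subregion = h, region = sub$region[1], tau = tt,
          beta0 = cf[1], beta1 = cf[2], slope_se = se, n = length(x),
          provenance = "huc4", se_method = se_method)
      })
    })
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  class(out) <- c("quantile_fits", class(out))
  out
}

# Linear quantile fit; returns c(intercept, slope).
rq_line <- function(x, y, tau) {
  fit <- suppressWarnings(quantreg::rq(y ~ x, tau = tau,
                                       data = data.frame(x = x, y = y)))
  unname(as.numeric(stats::coef(fit)))
}

# Slope standard error: paired bootstrap (default) or quantreg's nid.
rq_slope_se <- function(x, y, tau, method = "boot", n_boot = 100L, seed = 1L) {
  if (method == "nid") {
    s <- try(suppressWarnings(
      summary(quantreg::rq(y ~ x, tau = tau), se = "nid")), silent = TRUE)
    if (!inherits(s, "try-error")) return(as.numeric(s$coefficients["x", 2]))
    method <- "boot"
  }
  n <- length(x)
  slopes <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    if (diff(range(x[idx])) == 0) return(NA_real_)
    rq_line(x[idx], y[idx], tau)[2]
  }, numeric(1)))
  sd(slopes, na.rm = TRUE)
}

#' Region-mean fallback coefficients
#'
#' Where HUC-4 coefficients are unavailable, downstream reaches use the
#' unweighted mean of the region's HUC-4 coefficients per metric x tau;
#' slope SEs are pooled as the root mean square.
#'
#' @param fits a [fit_quantile_models()] table.
#' @return tibble of region-mean rows (`subregion` = region id,
#'   `provenance` = "region-mean").
#' @export
pool_region_coefficients <- function(fits) {
  if (nrow(fits) == 0L) {
    abort("no HUC-4 quantile fits to pool (all subregions skipped?)",
          class = "eflowalt_input_error")
  }
  fits %>%
    dplyr::group_by(.data$region, .data$metric, .data$tau) %>%
    dplyr::summarise(
      beta0 = mean(.data$beta0), beta1 = mean(.data$beta1),
      slope_se = sqrt(mean(.data$slope_se^2)),
      n = sum(.data$n), se_method = .data$se_method[1],
      .groups = "drop"
    ) %>%
    dplyr::mutate(subregion = .data$region, provenance = "region-mean") %>%
    dplyr::select("metric", "subregion", "region", "tau", "beta0", "beta1",
                  "slope_se", "n", "provenance", "se_method")
}

#' Tipping point of a fitted quantile line
#'
#' The alteration value at which the fitted quantile of richness residuals
#' crosses zero: `T = -beta0/beta1` clipped to \[0, 1\] for a declining
#' line (`beta1 < 0`); 0 when species are already being lost at zero
#' alteration (`beta0 < 0` with a non-declining line); undefined (`NA`)
#' when the line never crosses zero in \[0, 1\] (`beta1 >= 0, beta0 >= 0`).
#'
#' @param beta0,beta1 intercept and slope vectors.
#' @return numeric vector of thresholds (alteration units), `NA` where
#'   undefined.
#' @export
derive_threshold <- function(beta0, beta1) {
  out <- rep(NA_real_, length(beta0))
  dec <- beta1 < 0
  out[dec] <- clip01(-beta0[dec] / beta1[dec])
  nondec <- !dec & beta0 < 0
  out[nondec] <- 0
  out
}

#' Add tipping points (and bounds) to a quantile-fit table
#'
#' Applies [derive_threshold()] and [threshold_bounds()] rowwise.
#'
#' @param fits a [fit_quantile_models()] / [pool_region_coefficients()]
#'   table.
#' @return the table with `threshold`, `t_lower`, `t_upper` columns.
#' @export
derive_thresholds <- function(fits) {
  fits$threshold <- derive_threshold(fits$beta0, fits$beta1)
  tb <- threshold_bounds(fits$beta0, fits$beta1, fits$slope_se)
  fits$t_lower <- tb$t_lower
  fits$t_upper <- tb$t_upper
  fits
}

#' Resolve thresholds for each reach
#'
#' Each reach uses the quantile fit of its HUC-4 when available and the
#' region-mean fallback otherwise; reaches covered by neither are flagged
#' uncovered and excluded from summaries.
#'
#' @param thresholds a [derive_thresholds()] table containing both huc4 and
#'   region-mean rows.
#' @param reaches tibble with `comid_v1`, `huc4`, `region`.
#' @return long tibble: reach x metric x tau with coefficients, threshold
#'   and bounds, plus `coverage` ("huc4", "region-mean" or "uncovered").
#' @export
resolve_thresholds <- function(thresholds, reaches) {
  th_h <- thresholds[thresholds$provenance == "huc4", ]
  th_r <- thresholds[thresholds$provenance == "region-mean", ]
  keys <- reaches[, c("comid_v1", "huc4", "region")]
  via_h <- dplyr::inner_join(keys, th_h, by = c(huc4 = "subregion"),
                             relationship = "many-to-many")
  via_h$coverage <- "huc4"
  via_h <- dplyr::rename(via_h, region = "region.x")
  via_h$region.y <- NULL
  done <- unique(via_h[, c("comid_v1", "metric", "tau")])
  via_r <- dplyr::inner_join(keys, th_r, by = c(region = "subregion"),
                             relationship = "many-to-many")
  via_r$coverage <- "region-mean"
  via_r$region.y <- NULL
  via_r <- dplyr::anti_join(via_r, done, by = c("comid_v1", "metric", "tau"))
  out <- dplyr::bind_rows(via_h, via_r)
  uncovered <- setdiff(reaches$comid_v1, out$comid_v1)
  attr(out, "uncovered") <- uncovered
  out
}

#' Binary threshold exceedance per reach and metric
#'
#' `R = 1` when the reach's modeled alteration is greater than or equal to
#' the metric's resolved threshold (the boundary counts as loss);
#' metrics with undefined thresholds are excluded for that reach, shrinking
#' the metric count n rather than contributing 0.
#'
#' @param alteration long tibble of reach predictions (`comid_v1`,
#'   `metric`, `alteration_pred`).
#' @param resolved a [resolve_thresholds()] table.
#' @return long tibble reach x metric x tau with `threshold`, `exceed`
#'   (0/1) and the predicted `richness_delta` at the reach's alteration.
#' @export
classify_exceedance <- function(alteration, resolved) {
  keep <- intersect(c("comid_v1", "metric", "alteration_pred",
                      "ha_lower", "ha_upper"), names(alteration))
  df <- dplyr::inner_join(resolved, alteration[, keep],
                          by = c("comid_v1", "metric"))
  df <- df[!is.na(df$threshold) & !is.na(df$alteration_pred), , drop = FALSE]
  df$exceed <- as.integer(df$alteration_pred >= df$threshold)
  df$richness_delta <- df$beta0 + df$beta1 * df$alteration_pred
  df
}

#' Probability of fish biodiversity loss per reach
#'
#' The mean of the binary exceedance responses across hydrologic metrics
#' gives a per-reach loss probability in \[0, 1\]; the predicted richness
#' deltas are summarised by their median and minimum (most negative)
#' across metrics. Reaches with no defined metric return no row (missing,
#' not 0).
#'
#' @param exceedance table from [classify_exceedance()].
#' @return tibble `comid_v1`, `tau`, `n_metrics`, `p_loss`,
#'   `median_delta`, `min_delta`.
#' @export
loss_probability <- function(exceedance) {
  exceedance %>%
    dplyr::group_by(.data$comid_v1, .data$tau) %>%
    dplyr::summarise(
      n_metrics = dplyr::n(),
      p_loss = mean(.data$exceed),
      median_delta = median(.data$richness_delta),
      min_delta = min(.data$richness_delta),
      .groups = "drop"
    )
}

#' Tidy quantile-regression fits: one row per subregion x metric x tau
#' @param x a `quantile_fits` table.
#' @param ... unused.
#' @return tibble of coefficients.
#' @export
tidy.quantile_fits <- function(x, ...) {
  tibble::as_tibble(x)[, c("metric", "subregion", "tau", "beta0", "beta1",
                           "slope_se", "n")]
}

#' One-row summary of a quantile-fit table
#' @param x a `quantile_fits` table.
#' @param ... unused.
#' @return one-row tibble of fit counts.
#' @export
glance.quantile_fits <- function(x, ...) {
  tibble::tibble(
    n_fits = nrow(x),
    n_subregions = length(unique(x$subregion)),
    n_metrics = length(unique(x$metric)),
    taus = paste(sort(unique(x$tau)), collapse = ","),
    n_skipped = nrow(attr(x, "skipped") %||% tibble::tibble())
  )
}
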