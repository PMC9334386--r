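# Per-metric hydrologic alteration: observed vs expected index values,
# capped proportional change, plus the monthly-flow seasonality index.

#' Per-metric alteration from observed and expected index values
#'
#' For a point expectation E, alteration is `min(|(O - E)/E|, 1)`: the
#' absolute proportional change, with ratios above 1 assigned the maximum
#' value 1. For an interval expectation \[a, b\] (class-envelope fallback),
#' alteration is 0 when O lies inside the interval and otherwise the capped
#' proportional distance to the nearest bound. Conventions when the
#' comparison value is 0: O = 0 gives alteration 0, O > 0 gives 1.
#'
#' @param observed numeric vector of observed index values.
#' @param expected numeric vector of expected (point) values; ignored where
#'   `lower`/`upper` are given.
#' @param lower,upper optional interval expectations (either both `NA` or
#'   both set, elementwise).
#' @param is_reference logical; reference gauges short-circuit to 0.
#' @return numeric vector of alteration values in \[0, 1\].
#' @export
compute_alteration <- function(observed, expected = NULL, lower = NULL,
                               upper = NULL, is_reference = FALSE) {
  n <- length(observed)
  is_reference <- rep_len(is_reference, n)
  lower <- rep_len(lower %||% NA_real_, n)
  upper <- rep_len(upper %||% NA_real_, n)
  expected <- rep_len(expected %||% NA_real_, n)
  ratio_cap <- function(o, e) {
    out <- ifelse(e == 0, ifelse(o == 0, 0, 1), pmin(abs((o - e) / e), 1))
    out
  }
  interval <- !is.na(lower) & !is.na(upper)
  out <- rep(NA_real_, n)
  pt <- !interval & !is.na(expected)
  out[pt] <- ratio_cap(observed[pt], expected[pt])
  if (any(interval)) {
    o <- observed[interval]; a <- lower[interval]; b <- upper[interval]
    inside <- o >= a & o <= b
    nearest <- ifelse(o < a, a, b)
    v <- ifelse(inside, 0, ratio_cap(o, nearest))
    out[interval] <- v
  }
  out[is_reference] <- 0
  out
}

#' Seasonality alteration index from monthly flow means
#'
#' Cumulative proportional deviation of the 12 observed mean monthly flows
#' (MA12-MA23) from their expected values. The default sums the absolute
#' per-month deviations `|(O_i - E_i)/E_i|`; signed mode sums the raw
#' deviations, under which opposite-sign monthly shifts can cancel.
#' Months with E = 0 use the same convention as [compute_alteration()].
#'
#' @param observed,expected numeric vectors of 12 monthly means.
#' @param signed if `TRUE`, sum signed deviations instead of absolute.
#' @return raw (pre regional scaling) seasonality value.
#' @export
compute_seasonality <- function(observed, expected, signed = FALSE) {
  if (length(observed) != 12L || length(expected) != 12L) {
    abort("seasonality needs 12 observed and 12 expected monthly means",
          class = "eflowalt_input_error")
  }
  term <- ifelse(expected == 0,
                 ifelse(observed == 0, 0, 1),
                 (observed - expected) / expected)
  if (signed) sum(term) else sum(abs(term))
}

#' Min-max scale values within regions
#'
#' Applies `(x - min)/(max - min)` separately within each region, so the
#' scaled values span \[0, 1\] per region (rank-preserving). A region with
#' constant values maps to all zeros with a warning.
#'
#' @param x numeric vector.
#' @param region region labels (same length as `x`).
#' @return numeric vector scaled within region.
#' @export
minmax_scale_by_region <- function(x, region) {
  stopifnot(length(x) == length(region))
  out <- x
  for (r in unique(region)) {
    i <- which(region == r)
    out[i] <- minmax01(x[i], warn_constant = TRUE,
                       what = sprintf("values in region %s", r))
  }
  out
}

#' Estimate expected reference conditions at gauges
#'
#' For each hydrologic index, a random-forest regression is trained on
#' reference gauges using natural covariates only and used to predict the
#' expected value E at every gauge. Indices listed in `unreliable_metrics`
#' (by default the timing indices, for which point models are unreliable)
#' instead receive the central 90% interval (5th-95th percentile) of
#' reference values within the gauge's hydrologic class; classes with fewer
#' than two reference gauges inherit the global reference envelope with a
#' warning.
#'
#' @param metrics wide tibble: `gauge_id` plus one column per metric code
#'   (all gauges, reference and non-reference).
#' @param gauges tibble with `gauge_id`, `is_reference`, `hydro_class`.
#' @param covariates tibble with `unit_id` plus covariate columns; only the
#'   [natural_covariates()] columns present are used.
#' @param unreliable_metrics metric codes routed to the class envelope.
#' @param envelope_probs percentile pair for the class envelope.
#' @param ntree trees per forest.
#' @param seed integer seed for forest fitting.
#' @return long tibble: `gauge_id`, `metric`, `e_point`, `e_lower`,
#'   `e_upper`, `provenance` ("model" or "class-envelope").
#' @export
estimate_reference_conditions <- function(metrics, gauges, covariates,
                                          unreliable_metrics = c("TA1", "TA2"),
                                          envelope_probs = c(0.05, 0.95),
                                          ntree = 300L, seed = 1L) {
  ref_ids <- gauges$gauge_id[gauges$is_reference]
  if (length(ref_ids) == 0L) {
    abort("no reference gauges available", class = "eflowalt_reference_error")
  }
  nat_cols <- intersect(natural_covariates(), names(covariates))
  if (length(nat_cols) == 0L) {
    abort("covariate table has no natural covariate columns",
          class = "eflowalt_input_error")
  }
  cov <- covariates[match(metrics$gauge_id, covariates$unit_id), nat_cols,
                    drop = FALSE]
  if (anyNA(cov)) {
    abort("covariates missing for some gauges", class = "eflowalt_input_error")
  }
  met_cols <- intersect(metric_codes(), names(metrics))
  is_ref <- metrics$gauge_id %in% ref_ids
  gcl <- gauges$hydro_class[match(metrics$gauge_id, gauges$gauge_id)]
  seeds <- derive_seeds(seed, length(met_cols))

  out <- purrr::map2_dfr(met_cols, seeds, function(m, s) {
    y <- metrics[[m]]
    base <- tibble::tibble(gauge_id = metrics$gauge_id, metric = m,
                           e_point = NA_real_, e_lower = NA_real_,
                           e_upper = NA_real_, provenance = NA_character_)
    if (m %in% unreliable_metrics) {
      for (cl in unique(gcl)) {
        vals <- y[is_ref & gcl == cl & !is.na(y)]
        if (length(vals) < 2L) {
          warn(sprintf(
            "class %s has < 2 reference gauges for %s; using global envelope",
            cl, m))
          vals <- y[is_ref & !is.na(y)]
        }
        qs <- quantile(vals, envelope_probs, names = FALSE)
        i <- gcl == cl
        base$e_lower[i] <- qs[1]
        base$e_upper[i] <- qs[2]
      }
      base$provenance <- "class-envelope"
    } else {
      tr <- is_ref & !is.na(y)
      # near-constant responses (e.g. zero-flow-day counts at perennial
      # gauges) trigger randomForest's few-unique-values warning; harmless
      fit <- with_seed(s, suppressWarnings(randomForest::randomForest(
        x = as.data.frame(cov[tr, , drop = FALSE]), y = y[tr], ntree = ntree)))
      base$e_point <- as.numeric(predict(fit, as.data.frame(cov)))
      base$provenance <- "model"
    }
    base
  })
  out
}

#' Build the per-gauge alteration table
#'
#' Joins observed metric values to expected conditions and applies
#' [compute_alteration()]; reference gauges are set to 0 for every metric.
#'
#' @param metrics wide observed metric tibble (`gauge_id` + metric columns).
#' @param expected long tibble from [estimate_reference_conditions()].
#' @param gauges tibble with `gauge_id`, `is_reference`.
#' @return long tibble: `gauge_id`, `metric`, `observed`, `e_point`,
#'   `e_lower`, `e_upper`, `provenance`, `alteration`.
#' @export
alteration_table <- function(metrics, expected, gauges) {
  long <- tidyr::pivot_longer(
    metrics[, c("gauge_id", intersect(metric_codes(), names(metrics)))],
    -"gauge_id", names_to = "metric", values_to = "observed")
  df <- dplyr::left_join(long, expected, by = c("gauge_id", "metric"))
  df$is_reference <- gauges$is_reference[match(df$gauge_id, gauges$gauge_id)]
  df$alteration <- compute_alteration(df$observed, df$e_point, df$e_lower,
                                      df$e_upper, df$is_reference)
  df[, c("gauge_id", "metric", "observed", "e_point", "e_lower", "e_upper",
         "provenance", "alteration")]
}
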