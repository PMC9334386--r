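# Compounded uncertainty: forest-error bounds on alteration, slope-SE
# bounds on tipping points, bounded loss probabilities, and cumulative
# exceedance curves.

#' Error bounds on modeled alteration
#'
#' Adds and subtracts each model's out-of-bag error to the point
#' prediction, clipping to \[0, 1\]. The literal convention uses the MSE
#' itself; `use_rmse = TRUE` uses its square root, which is in alteration
#' units. Missing error values collapse the bounds onto the point with a
#' warning.
#'
#' @param predictions long tibble with `alteration_pred` and `mse` columns
#'   (e.g. from [predict_reach_alteration()]).
#' @param use_rmse use sqrt(MSE) instead of MSE.
#' @return the table with `ha_lower` and `ha_upper` columns.
#' @export
alteration_bounds <- function(predictions, use_rmse = FALSE) {
  err <- if (use_rmse) sqrt(predictions$mse) else predictions$mse
  if (anyNA(err)) {
    warn("missing model error for some predictions; bounds collapse to the point")
    err[is.na(err)] <- 0
  }
  predictions$ha_lower <- clip01(predictions$alteration_pred - err)
  predictions$ha_upper <- clip01(predictions$alteration_pred + err)
  predictions
}

#' Tipping-point bounds from slope standard errors
#'
#' The quantile-fit slope is varied by one standard error in each
#' direction and the zero crossing recomputed; the smaller crossing is the
#' minimum threshold and the larger the maximum, clipped to \[0, 1\]. When
#' the flattened slope `beta1 + se` reaches 0 the crossing escapes the unit
#' interval and the maximum is set to 1 (unless the intercept is already
#' negative, in which case the threshold is 0 at any slope). Bounds are
#' undefined where the point threshold is undefined.
#'
#' @param beta0,beta1,slope_se coefficient and SE vectors.
#' @return tibble with `t_lower`, `t_upper`.
#' @export
threshold_bounds <- function(beta0, beta1, slope_se) {
  cross_at <- function(b0, b1) {
    ifelse(b1 < 0, clip01(-b0 / b1), ifelse(b0 < 0, 0, 1))
  }
  defined <- !is.na(derive_threshold(beta0, beta1))
  c1 <- cross_at(beta0, beta1 - slope_se)
  c2 <- cross_at(beta0, beta1 + slope_se)
  tibble::tibble(
    t_lower = ifelse(defined, pmin(c1, c2), NA_real_),
    t_upper = ifelse(defined, pmax(c1, c2), NA_real_)
  )
}

#' Bounded probability of fish biodiversity loss
#'
#' Combines alteration bounds with threshold bounds per reach, metric and
#' tau. The default pairing is ordering-consistent: the lower-limit binary
#' response is 1 only when even the minimum alteration exceeds the maximum
#' threshold (loss certain under every error scenario), and the upper
#' -limit response is 1 when the maximum alteration exceeds the minimum
#' threshold (loss possible under some scenario). `literal_eq67 = TRUE`
#' instead applies the printed inequalities (minimum threshold vs maximum
#' alteration for the lower limit and vice versa), which reverses that
#' pairing; the mode used is recorded in the `pairing` attribute.
#'
#' @param exceedance table from [classify_exceedance()] computed on a
#'   prediction table that carries `ha_lower`/`ha_upper` (see
#'   [alteration_bounds()]); must contain `t_lower`, `t_upper`.
#' @param literal_eq67 use the printed-inequality pairing.
#' @return tibble `comid_v1`, `tau`, `n_metrics`, `p_loss`, `p_lower`,
#'   `p_upper`.
#' @export
loss_probability_bounds <- function(exceedance, literal_eq67 = FALSE) {
  need <- c("ha_lower", "ha_upper", "t_lower", "t_upper")
  miss <- setdiff(need, names(exceedance))
  if (length(miss)) {
    abort(sprintf("exceedance table missing bound columns: %s",
                  paste(miss, collapse = ", ")),
          class = "eflowalt_input_error")
  }
  df <- exceedance[!is.na(exceedance$t_lower), , drop = FALSE]
  if (literal_eq67) {
    df$r_lower <- as.integer(df$t_lower >= df$ha_upper)
    df$r_upper <- as.integer(df$t_upper >= df$ha_lower)
  } else {
    df$r_lower <- as.integer(df$ha_lower >= df$t_upper)
    df$r_upper <- as.integer(df$ha_upper >= df$t_lower)
  }
  out <- df %>%
    dplyr::group_by(.data$comid_v1, .data$tau) %>%
    dplyr::summarise(
      n_metrics = dplyr::n(),
      p_loss = mean(.data$exceed),
      p_lower = mean(.data$r_lower),
      p_upper = mean(.data$r_upper),
      .groups = "drop"
    )
  attr(out, "pairing") <- if (literal_eq67) "literal" else "ordering-consistent"
  out
}

#' Cumulative exceedance curve of loss probabilities
#'
#' For each grid value q in \[0, 1\], the (optionally weighted) proportion
#' of reaches whose loss probability is at least q. When lower/upper
#' probability columns are present the band curves are computed too. The
#' curve is non-increasing in q by construction.
#'
#' @param probabilities tibble with `p_loss` (and optionally `p_lower`,
#'   `p_upper`, `tau`); curves are computed per tau when present.
#' @param weights optional non-negative reach weights (e.g. stream length).
#' @param grid probability grid.
#' @return tibble of class `exceedance_curve`: `tau`, `q`, `prop`,
#'   `prop_lower`, `prop_upper`.
#' @export
cumulative_exceedance_curve <- function(probabilities, weights = NULL,
                                        grid = seq(0, 1, by = 0.01)) {
  if (nrow(probabilities) == 0L) {
    abort("no probabilities supplied", class = "eflowalt_input_error")
  }
  w <- weights %||% rep(1, nrow(probabilities))
  if (any(w < 0) || length(w) != nrow(probabilities)) {
    abort("weights must be non-negative, one per reach",
          class = "eflowalt_input_error")
  }
  taus <- if ("tau" %in% names(probabilities)) unique(probabilities$tau) else NA
  out <- purrr::map_dfr(taus, function(tt) {
    rows <- if (is.na(tt[1])) seq_len(nrow(probabilities)) else
      which(probabilities$tau == tt)
    p <- probabilities$p_loss[rows]
    wt <- w[rows] / sum(w[rows])
    prop_ge <- function(v) vapply(grid, function(q) sum(wt[v >= q]), numeric(1))
    tibble::tibble(
      tau = tt, q = grid,
      prop = prop_ge(p),
      prop_lower = if ("p_lower" %in% names(probabilities))
        prop_ge(probabilities$p_lower[rows]) else NA_real_,
      prop_upper = if ("p_upper" %in% names(probabilities))
        prop_ge(probabilities$p_upper[rows]) else NA_real_
    )
  })
  class(out) <- c("exceedance_curve", class(out))
  out
}
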