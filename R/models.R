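# Per-metric random-forest models of hydrologic alteration from the 50
# disturbance covariates, with the two rank-AUC validation measures,
# scaled permutation importance, and extrapolation to ungauged reaches.

#' Fit one alteration model (metric x scope)
#'
#' A random forest regresses the \[0, 1\] alteration response on the
#' covariate columns; out-of-bag predictions are retained for validation.
#' The alteration response is continuous in \[0, 1\], so the default mode is
#' regression with clipped predictions; `mode = "classification"` instead
#' fits a forest on the binarised response (`alteration > 0.5`) and predicts
#' class probabilities, for comparison.
#'
#' @param training tibble with `is_reference`, the covariate columns and
#'   the response column.
#' @param metric metric code the model is for (bookkeeping).
#' @param scope `"US"` or a region id (bookkeeping; filtering is the
#'   caller's job).
#' @param response name of the response column.
#' @param covariate_cols covariate column names (default: the registered
#'   [covariate_groups()] columns present in `training`).
#' @param mode `"regression"` (default) or `"classification"`.
#' @param ntree,mtry forest hyperparameters (`mtry` defaults to the
#'   randomForest regression default, p/3).
#' @param min_n minimum training rows; below it the scope is skipped and
#'   `NULL` returned with a message.
#' @param seed integer seed.
#' @return object of class `alteration_model`, or `NULL` when skipped.
#' @export
fit_alteration_model <- function(training, metric = NA_character_,
                                 scope = "US", response = "alteration",
                                 covariate_cols = NULL,
                                 mode = c("regression", "classification"),
                                 ntree = 500L, mtry = NULL, min_n = 20L,
                                 seed = 1L) {
  mode <- match.arg(mode)
  covariate_cols <- covariate_cols %||%
    intersect(covariate_groups()$covariate, names(training))
  if (length(covariate_cols) == 0L) {
    abort("no covariate columns found in training table",
          class = "eflowalt_input_error")
  }
  y <- training[[response]]
  ok <- !is.na(y)
  training <- training[ok, , drop = FALSE]
  y <- y[ok]
  if (nrow(training) < min_n) {
    inform(sprintf("scope %s for %s skipped: %d gauges < min_n = %d",
                   scope, metric, nrow(training), min_n))
    return(NULL)
  }
  if (any(y < 0 | y > 1)) {
    abort("alteration response must lie in [0, 1]", class = "eflowalt_input_error")
  }
  x <- as.data.frame(training[, covariate_cols, drop = FALSE])
  fit <- with_seed(seed, {
    if (mode == "classification") {
      yf <- factor(y > 0.5, levels = c(FALSE, TRUE))
      randomForest::randomForest(x = x, y = yf, ntree = ntree,
                                 mtry = mtry %||% floor(sqrt(ncol(x))),
                                 importance = TRUE)
    } else {
      # near-constant alteration responses trigger randomForest's
      # few-unique-values warning; harmless for [0,1] responses
      suppressWarnings(
        randomForest::randomForest(x = x, y = y, ntree = ntree,
                                   mtry = mtry %||% max(floor(ncol(x) / 3), 1),
                                   importance = TRUE))
    }
  })
  oob <- if (mode == "classification") {
    as.numeric(fit$votes[, "TRUE"])
  } else {
    clip01(as.numeric(fit$predicted))
  }
  mse <- mean((oob - y)^2)
  auc <- compute_auc_measures(oob, training$is_reference, y)
  raw_imp <- randomForest::importance(fit, type = 1)[, 1]
  imp <- tibble::tibble(
    covariate = names(raw_imp),
    raw_importance = as.numeric(raw_imp),
    ri = minmax01(as.numeric(raw_imp), warn_constant = TRUE,
                  what = "permutation importances")
  )
  imp <- dplyr::left_join(imp, covariate_groups(), by = "covariate")
  structure(
    list(metric = metric, scope = scope, fit = fit, mode = mode,
         n = nrow(training), oob = oob, observed = y,
         is_reference = training$is_reference, mse = mse,
         auc_measure1 = auc$auc_measure1, auc_measure2 = auc$auc_measure2,
         importance = imp, covariates = covariate_cols, seed = as.integer(seed),
         ntree = ntree),
    class = "alteration_model"
  )
}

#' @export
print.alteration_model <- function(x, ...) {
  cat(sprintf("<alteration_model> %s [%s], n = %d, OOB MSE = %.4f, AUC1 = %s, AUC2 = %s\n",
              x$metric, x$scope, x$n, x$mse,
              format(round(x$auc_measure1, 3)), format(round(x$auc_measure2, 3))))
  invisible(x)
}

#' The two rank-AUC validation measures
#'
#' Measure 1: how well predictions separate reference from non-reference
#' gauges (non-reference is the positive class). Measure 2: how well they
#' separate high (observed alteration > 0.5) from low (<= 0.5) gauges.
#' Both are midrank Mann-Whitney AUCs; a measure whose binary control has a
#' single class is returned as `NA` (undefined), not 0.
#'
#' @param oob out-of-bag (or other cross-validated) predictions.
#' @param is_reference logical reference flags.
#' @param observed observed alteration values.
#' @return list with `auc_measure1` and `auc_measure2`.
#' @export
compute_auc_measures <- function(oob, is_reference, observed) {
  list(
    auc_measure1 = rank_auc(oob, !is_reference),
    auc_measure2 = rank_auc(oob, observed > 0.5)
  )
}

#' Scaled relative importance of a model's covariates
#'
#' Permutation importances (mean OOB MSE increase) min-max scaled to
#' \[0, 1\] within the model, with the covariate group attached.
#'
#' @param model an `alteration_model`.
#' @return tibble `covariate`, `group`, `raw_importance`, `ri`.
#' @export
scaled_importance <- function(model) {
  model$importance[, c("covariate", "group", "raw_importance", "ri")]
}

#' Group-level importance summary across models
#'
#' Mean and standard error of scaled relative importance by covariate
#' group, per scope, across a list of fitted models.
#'
#' @param models list of `alteration_model` objects.
#' @return tibble `scope`, `group`, `mean_ri`, `se_ri`, `n_values`.
#' @export
importance_group_summary <- function(models) {
  models <- models[!vapply(models, is.null, logical(1))]
  purrr::map_dfr(models, function(m) {
    dplyr::mutate(scaled_importance(m), scope = m$scope, metric = m$metric)
  }) %>%
    dplyr::group_by(.data$scope, .data$group) %>%
    dplyr::summarise(
      mean_ri = mean(.data$ri),
      se_ri = sd(.data$ri) / sqrt(dplyr::n()),
      n_values = dplyr::n(),
      .groups = "drop"
    )
}

#' Fit alteration models for many metrics and scopes
#'
#' @param alteration long tibble from [alteration_table()] (`gauge_id`,
#'   `metric`, `alteration`).
#' @param covariates gauge covariate table (`unit_id` + covariates).
#' @param gauges tibble with `gauge_id`, `is_reference`, `region`.
#' @param scopes character vector: `"US"` and/or region ids.
#' @param metrics metric codes to model (default: all present).
#' @param ... passed to [fit_alteration_model()].
#' @param seed master seed; each metric x scope gets a derived sub-seed.
#' @return tibble with columns `metric`, `scope` and list-column `model`.
#' @export
fit_alteration_models <- function(alteration, covariates, gauges,
                                  scopes = "US", metrics = NULL, ...,
                                  seed = 1L) {
  metrics <- metrics %||% unique(alteration$metric)
  grid <- tidyr::expand_grid(metric = metrics, scope = scopes)
  seeds <- derive_seeds(seed, nrow(grid))
  cov_cols <- intersect(covariate_groups()$covariate, names(covariates))
  base <- dplyr::left_join(
    gauges[, c("gauge_id", "is_reference", "region")],
    covariates[covariates$unit_type %in% c("gauge", NA), ],
    by = c(gauge_id = "unit_id"))
  grid$model <- purrr::pmap(list(grid$metric, grid$scope, seeds),
    function(m, sc, s) {
      resp <- alteration[alteration$metric == m, c("gauge_id", "alteration")]
      tr <- dplyr::inner_join(base, resp, by = "gauge_id")
      if (sc != "US") tr <- tr[tr$region == sc, , drop = FALSE]
      fit_alteration_model(tr, metric = m, scope = sc,
                           covariate_cols = cov_cols, seed = s, ...)
    })
  grid
}

#' Predict alteration for ungauged reaches
#'
#' Applies fitted models to a reach covariate table. Under the regional
#' scope policy each reach uses its region's model when one exists and
#' falls back to the US-wide model otherwise (fallbacks are tagged); under
#' the US policy all reaches use the US model. Predictions are clipped to
#' \[0, 1\].
#'
#' @param models tibble from [fit_alteration_models()] (columns `metric`,
#'   `scope`, list-column `model`).
#' @param reach_covariates tibble with `unit_id`, `region` (for regional
#'   policy) and the training covariate columns.
#' @param scope_policy `"regional"` or `"US"`.
#' @return long tibble `comid_v1`, `region`, `metric`, `alteration_pred`,
#'   `scope_used`, `mse` (the OOB MSE of the model used).
#' @export
predict_reach_alteration <- function(models, reach_covariates,
                                     scope_policy = c("US", "regional")) {
  scope_policy <- match.arg(scope_policy)
  fitted <- models[!vapply(models$model, is.null, logical(1)), ]
  if (nrow(fitted) == 0L) abort("no fitted models", class = "eflowalt_input_error")
  need <- unique(unlist(lapply(fitted$model, `[[`, "covariates")))
  missing_cols <- setdiff(need, names(reach_covariates))
  if (length(missing_cols)) {
    abort(sprintf("reach covariates missing columns: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "eflowalt_schema_error", missing = missing_cols)
  }
  region <- reach_covariates$region %||% rep(NA_character_, nrow(reach_covariates))
  purrr::map_dfr(unique(fitted$metric), function(m) {
    sub <- fitted[fitted$metric == m, ]
    us_row <- which(sub$scope == "US")
    pick <- function(r) {
      if (scope_policy == "regional" && !is.na(r) && r %in% sub$scope) {
        which(sub$scope == r)
      } else {
        us_row
      }
    }
    rows <- vapply(region, function(r) {
      p <- pick(r); if (length(p)) p[1] else NA_integer_
    }, integer(1))
    out <- tibble::tibble(
      comid_v1 = reach_covariates$unit_id,
      region = region,
      metric = m,
      alteration_pred = NA_real_,
      scope_used = NA_character_,
      mse = NA_real_
    )
    for (j in unique(rows[!is.na(rows)])) {
      mdl <- sub$model[[j]]
      i <- which(rows == j)
      newx <- as.data.frame(reach_covariates[i, mdl$covariates, drop = FALSE])
      pred <- if (mdl$mode == "classification") {
        predict(mdl$fit, newx, type = "prob")[, "TRUE"]
      } else {
        predict(mdl$fit, newx)
      }
      out$alteration_pred[i] <- clip01(as.numeric(pred))
      out$scope_used[i] <- sub$scope[j]
      out$mse[i] <- mdl$mse
    }
    out
  })
}

#' Tidy an alteration model: scaled covariate importance
#' @param x an `alteration_model`.
#' @param ... unused.
#' @return tibble of per-covariate importance.
#' @export
tidy.alteration_model <- function(x, ...) scaled_importance(x)

#' One-row performance summary of an alteration model
#' @param x an `alteration_model`.
#' @param ... unused.
#' @return one-row tibble with OOB MSE and the two AUC measures.
#' @export
glance.alteration_model <- function(x, ...) {
  tibble::tibble(metric = x$metric, scope = x$scope, mode = x$mode,
                 n = x$n, mse = x$mse, auc_measure1 = x$auc_measure1,
                 auc_measure2 = x$auc_measure2, ntree = x$ntree)
}
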