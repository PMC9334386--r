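# Cumulative hydrologic alteration index (HAI): PCA of scaled metrics,
# broken-stick component significance, per-class reference score envelopes,
# and eigenvalue-weighted envelope excursions.

#' Broken-stick count of significant principal components
#'
#' With p components, the broken-stick expectation for component j is
#' `b_j = (1/p) * sum_{i=j..p} 1/i`. Components are significant while their
#' observed variance proportion strictly exceeds `b_j`, stopping at the
#' first failure.
#'
#' @param eigenvalues non-negative, non-increasing eigenvalues.
#' @return integer count `k` of significant leading components.
#' @export
broken_stick <- function(eigenvalues) {
  p <- length(eigenvalues)
  if (p == 0L) return(0L)
  if (any(diff(eigenvalues) > 1e-8) || any(eigenvalues < 0)) {
    abort("eigenvalues must be non-negative and non-increasing",
          class = "eflowalt_input_error")
  }
  total <- sum(eigenvalues)
  if (total <= 0) {
    warn("all eigenvalues are zero; no significant components")
    return(0L)
  }
  prop <- eigenvalues / total
  b <- rev(cumsum(1 / rev(seq_len(p)))) / p
  k <- 0L
  for (j in seq_len(p)) {
    if (prop[j] > b[j]) k <- j else break
  }
  k
}

#' Fit the reference PCA and class score envelopes
#'
#' Each metric column is min-max scaled to \[0, 1\] and centred; PCA is fit
#' on all gauges (reference and non-reference jointly). The number of
#' significant components comes from [broken_stick()]; per-class envelopes
#' are the 5th-95th percentiles of reference-gauge scores on each
#' significant component. PC signs follow the convention that the
#' largest-magnitude loading is positive.
#'
#' @param metrics wide tibble: `gauge_id` plus metric columns.
#' @param gauges tibble with `gauge_id`, `is_reference`, `hydro_class`.
#' @param envelope_probs percentile pair for the reference envelopes.
#' @param min_k floor on the number of components used for HAI (the
#'   broken-stick count can be 0 on weakly structured tables; at least one
#'   component is retained by default so the index stays defined).
#' @return object of class `reference_pca`.
#' @export
fit_reference_pca <- function(metrics, gauges, envelope_probs = c(0.05, 0.95),
                              min_k = 1L) {
  met_cols <- intersect(metric_codes(), names(metrics))
  x <- as.matrix(metrics[, met_cols])
  if (nrow(x) < 3L) abort("PCA needs at least 3 gauges", class = "eflowalt_input_error")
  keep <- apply(x, 2, function(col) {
    all(is.finite(col)) && diff(range(col)) > 0
  })
  if (any(!keep)) {
    warn(sprintf("dropping constant or non-finite metric columns: %s",
                 paste(met_cols[!keep], collapse = ", ")))
  }
  x <- x[, keep, drop = FALSE]
  met_cols <- met_cols[keep]
  col_min <- apply(x, 2, min)
  col_max <- apply(x, 2, max)
  xs <- sweep(sweep(x, 2, col_min), 2, col_max - col_min, "/")
  pc <- prcomp(xs, center = TRUE, scale. = FALSE)
  # sign convention: largest-|loading| entry positive on every component
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, "*")
  pc$x <- sweep(pc$x, 2, flip, "*")
  ev <- pc$sdev^2
  k <- broken_stick(ev)
  k_used <- max(k, as.integer(min_k))
  k_used <- min(k_used, ncol(pc$x))

  is_ref <- gauges$is_reference[match(metrics$gauge_id, gauges$gauge_id)]
  gcl <- gauges$hydro_class[match(metrics$gauge_id, gauges$gauge_id)]
  env <- purrr::map_dfr(unique(gcl), function(cl) {
    ref_rows <- which(is_ref & gcl == cl)
    pooled <- FALSE
    if (length(ref_rows) < 2L) {
      warn(sprintf("class %s has < 2 reference gauges; envelope pooled from all references", cl))
      ref_rows <- which(is_ref)
      pooled <- TRUE
    }
    purrr::map_dfr(seq_len(k_used), function(i) {
      qs <- quantile(pc$x[ref_rows, i], envelope_probs, names = FALSE)
      tibble::tibble(hydro_class = cl, component = i, a = qs[1], b = qs[2],
                     pooled = pooled)
    })
  })
  scores <- tibble::as_tibble(pc$x[, seq_len(k_used), drop = FALSE])
  names(scores) <- paste0("PC", seq_len(k_used))
  scores <- dplyr::bind_cols(
    tibble::tibble(gauge_id = metrics$gauge_id, hydro_class = gcl,
                   is_reference = is_ref), scores)
  structure(
    list(metrics = met_cols, col_min = col_min, col_max = col_max,
         center = pc$center, rotation = pc$rotation, eigenvalues = ev,
         k = k, k_used = k_used, envelopes = env, scores = scores,
         envelope_probs = envelope_probs),
    class = "reference_pca"
  )
}

#' @export
print.reference_pca <- function(x, ...) {
  cat(sprintf("<reference_pca> %d metrics, %d significant components (broken stick), %d used\n",
              length(x$metrics), x$k, x$k_used))
  invisible(x)
}

#' Project gauges onto a fitted reference PCA
#'
#' @param pca a [fit_reference_pca()] object.
#' @param metrics wide tibble with `gauge_id` and the PCA's metric columns.
#' @return tibble `gauge_id` + `PC1..PCk` scores.
#' @export
score_gauges <- function(pca, metrics) {
  x <- as.matrix(metrics[, pca$metrics])
  xs <- sweep(sweep(x, 2, pca$col_min), 2, pca$col_max - pca$col_min, "/")
  xs <- sweep(xs, 2, pca$center)
  sc <- xs %*% pca$rotation[, seq_len(pca$k_used), drop = FALSE]
  out <- tibble::as_tibble(sc)
  names(out) <- paste0("PC", seq_len(pca$k_used))
  dplyr::bind_cols(tibble::tibble(gauge_id = metrics$gauge_id), out)
}

#' Raw HAI from scores, envelopes and eigenvalues
#'
#' For each significant component i with reference envelope (a_i, b_i) and
#' eigenvalue V_i, the rank is r_i = 0 when a_i <= S_i <= b_i and V_i
#' otherwise; the raw HAI is the sum of `|S_i - nearest violated bound| * r_i`.
#' Scores inside every envelope give 0.
#'
#' @param scores numeric vector S_1..S_k for one gauge.
#' @param a,b envelope bounds per component.
#' @param eigenvalues V_1..V_k.
#' @return non-negative raw HAI.
#' @export
compute_hai <- function(scores, a, b, eigenvalues) {
  stopifnot(length(scores) == length(a), length(a) == length(b),
            length(b) == length(eigenvalues))
  below <- scores < a
  above <- scores > b
  sum(abs(scores - a) * eigenvalues * below) +
    sum(abs(scores - b) * eigenvalues * above)
}

#' Per-gauge raw HAI for a network
#'
#' Looks up each gauge's class envelopes in the fitted PCA and applies
#' [compute_hai()].
#'
#' @param pca a [fit_reference_pca()] object.
#' @param scores tibble from the PCA (`pca$scores`) or [score_gauges()]
#'   joined with `hydro_class`.
#' @return tibble `gauge_id`, `hai_raw`.
#' @export
hai_table <- function(pca, scores = pca$scores) {
  if (!"hydro_class" %in% names(scores)) {
    abort("scores must carry a hydro_class column", class = "eflowalt_input_error")
  }
  pcs <- paste0("PC", seq_len(pca$k_used))
  ev <- pca$eigenvalues[seq_len(pca$k_used)]
  hai <- vapply(seq_len(nrow(scores)), function(i) {
    env <- pca$envelopes[pca$envelopes$hydro_class == scores$hydro_class[i], ]
    env <- env[order(env$component), ]
    compute_hai(as.numeric(scores[i, pcs]), env$a, env$b, ev)
  }, numeric(1))
  tibble::tibble(gauge_id = scores$gauge_id, hai_raw = hai)
}
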