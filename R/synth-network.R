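# Synthetic gauge/reach network generator. The generator is the testing
# backbone: it produces a network whose flows, covariates and fish responses
# have the statistical structure the downstream analysis assumes, with known
# ground truth.

#' Generate a synthetic gauge and reach network
#'
#' Gauges and reaches are assigned cyclically to ecohydrologic regions (so
#' every region is non-empty whenever `n_gauges >= n_regions`) and randomly
#' to hydrologic classes and to one of two HUC-4 watersheds per region.
#' A fixed fraction of gauges is flagged as reference (least-disturbed);
#' reference gauges carry an all-zero disturbance profile, non-reference
#' gauges draw dam-storage, withdrawal, urban-flashiness and seasonal-shift
#' intensities independently.
#'
#' @param n_gauges,n_reaches number of gauges / ungauged reaches.
#' @param n_regions,n_classes number of ecohydrologic regions / hydrologic
#'   classes.
#' @param reference_fraction fraction of gauges in reference condition
#'   (0 < f < 1); the realised count is `round(n_gauges * f)`.
#' @param seed integer seed; the network is a pure function of the
#'   arguments and this seed.
#' @return a list of class `gauge_network` with tibbles `gauges` and
#'   `reaches` plus `regions` and `classes` vectors. Disturbance columns:
#'   `dam_storage_intensity`, `withdrawal_fraction`, `urban_flashiness`
#'   (all in \[0,1\]), `seasonal_shift_months` (integer 0-6) and their
#'   summary `disturbance_total`.
#' @export
generate_gauge_network <- function(n_gauges, n_reaches = 0L, n_regions = 4L,
                                   n_classes = 4L, reference_fraction = 0.4,
                                   seed = 1L) {
  if (n_gauges < 2L || n_regions < 1L || n_classes < 1L || n_reaches < 0L) {
    abort("counts must be positive (n_gauges >= 2)", class = "eflowalt_input_error")
  }
  if (reference_fraction <= 0 || reference_fraction >= 1) {
    abort("reference_fraction must lie strictly between 0 and 1",
          class = "eflowalt_input_error")
  }
  regions <- sprintf("R%02d", seq_len(n_regions))
  classes <- sprintf("C%02d", seq_len(n_classes))
  huc4_of <- function(region_idx, draw) sprintf("%02d%02d", region_idx, draw)

  with_seed(seed, {
    n_ref <- round(n_gauges * reference_fraction)
    ref_idx <- sample.int(n_gauges, n_ref)
    region_idx <- rep_len(seq_len(n_regions), n_gauges)
    gauges <- tibble::tibble(
      gauge_id = sprintf("G%05d", seq_len(n_gauges)),
      is_reference = seq_len(n_gauges) %in% ref_idx,
      region = regions[region_idx],
      huc4 = huc4_of(region_idx, sample(1:2, n_gauges, replace = TRUE)),
      hydro_class = classes[sample.int(n_classes, n_gauges, replace = TRUE)],
      drainage_area = exp(rnorm(n_gauges, log(250), 0.6)),
      dam_storage_intensity = runif(n_gauges, 0, 0.9),
      withdrawal_fraction = runif(n_gauges, 0, 0.6),
      urban_flashiness = runif(n_gauges, 0, 0.8),
      seasonal_shift_months = sample(0:2, n_gauges, replace = TRUE,
                                     prob = c(0.6, 0.3, 0.1))
    )
    dist_cols <- c("dam_storage_intensity", "withdrawal_fraction",
                   "urban_flashiness", "seasonal_shift_months")
    gauges[gauges$is_reference, dist_cols] <- 0
    gauges$seasonal_shift_months <- as.integer(gauges$seasonal_shift_months)
    gauges$disturbance_total <- (gauges$dam_storage_intensity +
      gauges$withdrawal_fraction + gauges$urban_flashiness) / 3

    reaches <- if (n_reaches > 0L) {
      r_region_idx <- rep_len(seq_len(n_regions), n_reaches)
      r <- tibble::tibble(
        comid_v1 = sprintf("%07d", seq_len(n_reaches)),
        comid_v2 = sprintf("2%06d", seq_len(n_reaches)),
        region = regions[r_region_idx],
        huc4 = huc4_of(r_region_idx, sample(1:2, n_reaches, replace = TRUE)),
        hydro_class = classes[sample.int(n_classes, n_reaches, replace = TRUE)],
        drainage_area = exp(rnorm(n_reaches, log(250), 0.6)),
        dam_storage_intensity = runif(n_reaches, 0, 0.9),
        withdrawal_fraction = runif(n_reaches, 0, 0.6),
        urban_flashiness = runif(n_reaches, 0, 0.8),
        seasonal_shift_months = as.integer(sample(0:2, n_reaches, replace = TRUE,
                                                  prob = c(0.6, 0.3, 0.1)))
      )
      # a slice of reaches is effectively undisturbed, mirroring the gauges
      undist <- runif(n_reaches) < reference_fraction / 2
      r[undist, c("dam_storage_intensity", "withdrawal_fraction",
                  "urban_flashiness", "seasonal_shift_months")] <- 0
      r$seasonal_shift_months <- as.integer(r$seasonal_shift_months)
      r$disturbance_total <- (r$dam_storage_intensity + r$withdrawal_fraction +
        r$urban_flashiness) / 3
      r
    } else {
      tibble::tibble()
    }
    structure(
      list(gauges = gauges, reaches = reaches, regions = regions,
           classes = classes, seed = as.integer(seed)),
      class = "gauge_network"
    )
  })
}

#' @export
print.gauge_network <- function(x, ...) {
  cat(sprintf(
    "<gauge_network> %d gauges (%d reference), %d reaches, %d regions, %d classes\n",
    nrow(x$gauges), sum(x$gauges$is_reference), nrow(x$reaches),
    length(x$regions), length(x$classes)))
  invisible(x)
}

#' Covariate registry: 50 predictors in 8 groups
#'
#' The covariate table mimics the usual basin-disturbance predictor stack:
#' urbanization (14 columns), agriculture (10), dams and reservoirs (6),
#' power generation (6), dischargers and flow modifiers (5), composite
#' human-disturbance indices (3), basin/stream/climate descriptors (3) and
#' natural land cover (3).
#'
#' @return tibble with columns `covariate` and `group`.
#' @export
covariate_groups <- function() {
  tibble::tibble(
    covariate = c(sprintf("urb_%02d", 1:14), sprintf("ag_%02d", 1:10),
                  sprintf("dam_%02d", 1:6), sprintf("pow_%02d", 1:6),
                  sprintf("dis_%02d", 1:5), sprintf("hdi_%02d", 1:3),
                  sprintf("bsc_%02d", 1:3), sprintf("nat_%02d", 1:3)),
    group = c(rep("urbanization", 14), rep("agriculture", 10),
              rep("dams_reservoirs", 6), rep("power", 6),
              rep("dischargers", 5), rep("disturbance_index", 3),
              rep("basin_climate", 3), rep("natural_cover", 3))
  )
}

#' Names of the natural (disturbance-free) covariates
#' @return character vector (basin/climate and natural-cover columns).
#' @export
natural_covariates <- function() {
  g <- covariate_groups()
  g$covariate[g$group %in% c("basin_climate", "natural_cover")]
}

#' Generate the 50-column covariate table for a network
#'
#' Disturbance-group columns are noisy monotone transforms (powers 0.5, 1,
#' 2 cycled within each group) of the true disturbance intensities; the
#' composite indices track mean total disturbance; basin/climate and
#' natural-cover columns are deterministic functions of drainage area and
#' hydrologic class only, so they are legitimate predictors of reference
#' conditions.
#'
#' @param network a [generate_gauge_network()] result.
#' @param noise_sd Gaussian noise added to each disturbance-linked column
#'   (0 gives perfect rank correlation with the underlying intensity).
#' @param seed integer seed.
#' @return tibble with `unit_id`, `unit_type` ("gauge"/"reach") and the 50
#'   covariate columns of [covariate_groups()].
#' @export
generate_covariates <- function(network, noise_sd = 0.05, seed = 1L) {
  units <- dplyr::bind_rows(
    dplyr::mutate(dplyr::rename(network$gauges, unit_id = "gauge_id"),
                  unit_type = "gauge"),
    if (nrow(network$reaches)) {
      dplyr::mutate(dplyr::rename(network$reaches, unit_id = "comid_v1"),
                    unit_type = "reach")
    }
  )
  if (nrow(units) == 0L) abort("empty network", class = "eflowalt_input_error")
  n <- nrow(units)
  class_idx <- match(units$hydro_class, network$classes)
  total <- (units$dam_storage_intensity + units$withdrawal_fraction +
            units$urban_flashiness) / 3
  pw <- function(i) c(1, 0.5, 2)[(i - 1L) %% 3L + 1L]

  with_seed(seed, {
    noisy <- function(base, i) base^pw(i) + rnorm(n, 0, noise_sd)
    cols <- list()
    for (i in 1:14) cols[[sprintf("urb_%02d", i)]] <- noisy(units$urban_flashiness, i)
    for (i in 1:10) cols[[sprintf("ag_%02d", i)]] <-
      noisy(0.4 * units$withdrawal_fraction + 0.1 * units$urban_flashiness, i)
    for (i in 1:6) cols[[sprintf("dam_%02d", i)]] <- noisy(units$dam_storage_intensity, i)
    for (i in 1:6) cols[[sprintf("pow_%02d", i)]] <-
      noisy(0.5 * units$dam_storage_intensity, i)
    for (i in 1:5) cols[[sprintf("dis_%02d", i)]] <- noisy(units$withdrawal_fraction, i)
    for (i in 1:3) cols[[sprintf("hdi_%02d", i)]] <- noisy(total, i)
    cols[["bsc_01"]] <- log(units$drainage_area)
    cols[["bsc_02"]] <- class_idx / length(network$classes)
    cols[["bsc_03"]] <- sqrt(units$drainage_area)
    cols[["nat_01"]] <- 1 / (1 + units$drainage_area / 250)
    cols[["nat_02"]] <- sin(pi * class_idx / (length(network$classes) + 1))
    cols[["nat_03"]] <- log(units$drainage_area) * class_idx /
      length(network$classes)
    dplyr::bind_cols(
      tibble::tibble(unit_id = units$unit_id, unit_type = units$unit_type),
      tibble::as_tibble(cols)
    )
  })
}
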