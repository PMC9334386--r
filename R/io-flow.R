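# Readers/writers for daily discharge (NWIS RDB dialect and plain CSV) and
# the NHDPlus V1 -> V2 reach-identifier crosswalk.

CFS_TO_CMS <- 0.028316846592

#' Read a daily discharge record
#'
#' Supports plain CSV (`date,discharge` header) and the tab-delimited NWIS
#' RDB dialect (comment lines starting `#`, a header row, and a type row
#' such as `5s 15s 10d 14n` which is skipped). Non-numeric discharge codes
#' (provisional/ice/missing markers) become `NA`; 29 February rows are
#' dropped (count recorded in the `n_leap_dropped` attribute); negative
#' discharge raises a typed error naming the offending lines.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"nwis-rdb"`; `"auto"` sniffs (a leading `#`
#'   or tab-separated header means RDB).
#' @param units units of the file's discharge values.
#' @param to_units convert to these units on read (default: keep).
#' @param gauge_id,drainage_area metadata attached to the series.
#' @return a [daily_flow_series()].
#' @export
read_daily_flow <- function(path, dialect = c("auto", "csv", "nwis-rdb"),
                            units = c("cfs", "cms"), to_units = NULL,
                            gauge_id = NA_character_,
                            drainage_area = NA_real_) {
  dialect <- match.arg(dialect)
  units <- match.arg(units)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "eflowalt_input_error")
  }
  lines <- readLines(path, warn = FALSE)
  if (dialect == "auto") {
    dialect <- if (any(startsWith(lines, "#")) || grepl("\t", lines[1]))
      "nwis-rdb" else "csv"
  }
  if (dialect == "nwis-rdb") {
    body <- lines[!startsWith(lines, "#")]
    if (length(body) < 2L) abort("RDB file has no data rows", class = "eflowalt_input_error")
    header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
    rows <- body[-1]
    # the RDB column-type row looks like "5s\t15s\t10d\t14n"
    if (length(rows) && grepl("^\\s*\\d+[a-z]", rows[1])) rows <- rows[-1]
    mat <- do.call(rbind, strsplit(rows, "\t", fixed = TRUE))
    df <- tibble::as_tibble(as.data.frame(mat, stringsAsFactors = FALSE))
    names(df) <- header[seq_len(ncol(df))]
    date_col <- intersect(c("datetime", "date"), names(df))[1]
    q_col <- setdiff(names(df), c("agency_cd", "site_no", date_col, "cd",
                                  "qualification_cd"))[1]
    if (is.na(date_col) || is.na(q_col)) {
      abort("could not locate date/discharge columns in RDB file",
            class = "eflowalt_input_error")
    }
    raw_date <- df[[date_col]]
    raw_q <- df[[q_col]]
    if ("site_no" %in% names(df) && is.na(gauge_id)) gauge_id <- df$site_no[1]
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
    date_col <- intersect(c("date", "datetime"), names(df))[1]
    q_col <- intersect(c("discharge", "flow", "q"), names(df))[1]
    if (is.na(date_col) || is.na(q_col)) {
      abort("CSV must have date and discharge columns",
            class = "eflowalt_input_error")
    }
    raw_date <- df[[date_col]]
    raw_q <- df[[q_col]]
  }
  date <- as.Date(raw_date, format = "%Y-%m-%d")
  bad_date <- which(is.na(date) & !is.na(raw_date) & raw_date != "")
  if (length(bad_date)) {
    abort(sprintf("unparseable dates on data lines: %s",
                  paste(head(bad_date, 5), collapse = ", ")),
          class = "eflowalt_parse_error", lines = bad_date)
  }
  q <- suppressWarnings(as.numeric(raw_q))
  neg <- which(q < 0)
  if (length(neg)) {
    abort(sprintf("negative discharge on data lines: %s",
                  paste(head(neg, 5), collapse = ", ")),
          class = "eflowalt_parse_error", lines = neg)
  }
  leap <- format(date, "%m-%d") == "02-29"
  n_leap <- sum(leap)
  date <- date[!leap]; q <- q[!leap]
  if (!is.null(to_units) && to_units != units) {
    fac <- if (units == "cfs" && to_units == "cms") CFS_TO_CMS else 1 / CFS_TO_CMS
    q <- q * fac
    units <- to_units
  }
  ord <- order(date)
  out <- daily_flow_series(date[ord], q[ord], gauge_id = gauge_id,
                           units = units, drainage_area = drainage_area)
  attr(out, "n_leap_dropped") <- n_leap
  out
}

#' Write a daily discharge record
#'
#' @param series a `daily_flow` series.
#' @param path output path.
#' @param dialect `"csv"` (`date,discharge`) or `"nwis-rdb"` (tab-delimited
#'   with comment header and type row).
#' @return `path`, invisibly.
#' @export
write_daily_flow <- function(series, path, dialect = c("csv", "nwis-rdb")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    readr::write_csv(tibble::tibble(date = series$date,
                                    discharge = series$discharge), path)
  } else {
    gid <- flow_attr(series, "gauge_id") %||% "NA"
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "# synthetic daily discharge, NWIS RDB dialect",
      sprintf("# units: %s", flow_attr(series, "units")),
      "agency_cd\tsite_no\tdatetime\tdischarge",
      "5s\t15s\t10d\t14n",
      sprintf("USGS\t%s\t%s\t%s", gid, format(series$date, "%Y-%m-%d"),
              format(series$discharge, trim = TRUE, scientific = FALSE))
    ), con)
  }
  invisible(path)
}

#' Attach NHDPlus V2 identifiers via a crosswalk table
#'
#' One-to-many V1 -> V2 mappings duplicate the row with a `multi_match`
#' flag; V1 identifiers absent from the crosswalk keep a missing V2 id and
#' are counted in the `crosswalk_report` attribute. Exact duplicate
#' crosswalk pairs are collapsed.
#'
#' @param table tibble keyed by `comid_v1`.
#' @param crosswalk tibble with columns `comid_v1`, `comid_v2`.
#' @return `table` with `comid_v2` and `multi_match` columns.
#' @export
crosswalk_comids <- function(table, crosswalk) {
  if (!all(c("comid_v1", "comid_v2") %in% names(crosswalk))) {
    abort("crosswalk must have comid_v1 and comid_v2 columns",
          class = "eflowalt_input_error")
  }
  if (anyNA(crosswalk$comid_v1)) {
    abort("crosswalk has missing comid_v1 keys", class = "eflowalt_input_error")
  }
  cw <- dplyr::distinct(crosswalk[, c("comid_v1", "comid_v2")])
  counts <- table(cw$comid_v1)
  tbl <- table
  tbl$comid_v2 <- NULL
  out <- dplyr::left_join(tbl, cw, by = "comid_v1",
                          relationship = "many-to-many")
  out$multi_match <- counts[out$comid_v1] > 1
  out$multi_match[is.na(out$multi_match)] <- FALSE
  n_unmatched <- sum(is.na(out$comid_v2))
  attr(out, "crosswalk_report") <- tibble::tibble(
    n_input = nrow(table), n_output = nrow(out), n_unmatched = n_unmatched,
    n_multi = sum(out$multi_match))
  out
}
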