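#' Read submaximal test records from CSV
#'
#' Expects one row per test with columns `id`, `sex` (M/F or male/female),
#' `age`, `hr_standard`, `hr_high`, and work rates either in watts
#' (`po_standard_w`, `po_high_w`; bare `po_standard`/`po_high` also
#' accepted) or as ergometer settings (`kp_standard`, `kp_high`, `rpm`),
#' which are converted with [kp_rpm_to_watts()]. Optional columns:
#' `body_mass_kg` (or `body_mass`) and `measured_vo2max_l_min` (or
#' `measured_vo2max`). Unknown extra columns are preserved. Rows failing
#' the record invariants are dropped and reported in the `"problems"`
#' attribute with their row numbers.
#'
#' @param path CSV path (comma-separated, UTF-8, '.' decimal separator).
#' @return a validated record tibble (see [test_records()]).
#' @export
read_records <- function(path) {
  if (!file.exists(path)) {
    stop("I/O error: file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  raw <- rename_alias(raw, "po_standard", "po_standard_w")
  raw <- rename_alias(raw, "po_high", "po_high_w")
  raw <- rename_alias(raw, "body_mass", "body_mass_kg")
  raw <- rename_alias(raw, "measured_vo2max", "measured_vo2max_l_min")
  has_watts <- all(c("po_standard", "po_high") %in% names(raw))
  has_kp <- all(c("kp_standard", "kp_high", "rpm") %in% names(raw))
  if (!has_watts && has_kp) {
    raw$po_standard <- kp_rpm_to_watts(raw$kp_standard, raw$rpm)
    raw$po_high <- kp_rpm_to_watts(raw$kp_high, raw$rpm)
  } else if (!has_watts) {
    stop("format error: missing required column(s) po_standard_w, po_high_w ",
         "(or kp_standard, kp_high, rpm)", call. = FALSE)
  }
  required <- c("sex", "age", "hr_standard", "hr_high")
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0) {
    stop("format error: missing required column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  test_records(raw)
}

rename_alias <- function(df, canonical, alias) {
  if (!canonical %in% names(df) && alias %in% names(df)) {
    names(df)[names(df) == alias] <- canonical
  }
  df
}

#' Write estimates to CSV
#'
#' Serialises an estimate tibble (see [eb_new_estimate()]). By default the
#' reported precision follows the conventional tables: 2 decimals for
#' absolute VO2max (L/min) and 1 decimal for relative (mL/kg/min); pass
#' `digits_abs = NA` to keep full precision. The `warnings` column is a
#' semicolon-joined string (empty allowed), so the file round-trips with
#' [readr::read_csv()].
#'
#' @param estimates an estimate tibble.
#' @param path output CSV path.
#' @param digits_abs,digits_rel rounding for the absolute and relative
#'   columns; `NA` for no rounding.
#' @return the written tibble, invisibly.
#' @export
write_estimates <- function(estimates, path, digits_abs = 2, digits_rel = 1) {
  out <- estimates
  if (!is.na(digits_abs) && "vo2max_abs" %in% names(out)) {
    out$vo2max_abs <- round(out$vo2max_abs, digits_abs)
  }
  if (!is.na(digits_rel) && "vo2max_rel" %in% names(out)) {
    out$vo2max_rel <- round(out$vo2max_rel, digits_rel)
  }
  readr::write_csv(out, path)
  invisible(out)
}

#' Write an agreement report to versioned JSON
#'
#' @param report a one-row [agreement_report()] tibble or a
#'   [stratified_report()] table.
#' @param path output JSON path.
#' @param meta optional named list merged into the header (e.g. method,
#'   seed).
#' @return the path, invisibly.
#' @export
write_report <- function(report, path, meta = list()) {
  payload <- c(list(schema = "ebtest-agreement-report",
                    schema_version = "1.0",
                    package_version =
                      as.character(utils::packageVersion("ebtest"))),
               meta,
               list(report = report))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read back a JSON agreement report
#'
#' @param path a JSON file written by [write_report()].
#' @return a list with the header fields and the `report` tibble.
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "ebtest-agreement-report")) {
    stop("format error: not an ebtest agreement report", call. = FALSE)
  }
  payload$report <- tibble::as_tibble(payload$report)
  payload
}
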