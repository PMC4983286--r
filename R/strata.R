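#' Sex-specific fitness-quartile cut-points
#'
#' The default cut-points are the published model-group quartiles of
#' measured VO2max: absolute (L/min) women 2.14 / 2.59 / 2.93 and men
#' 3.07 / 3.75 / 4.33; relative (mL/kg/min) women 32.5 / 40.2 / 47.4 and
#' men 37.5 / 47.6 / 54.8. A value equal to a cut-point is assigned to the
#' higher quartile.
#'
#' @param absolute named list of increasing length-3 cut vectors (`male`,
#'   `female`), L/min.
#' @param relative same for relative VO2max, mL/kg/min.
#' @return an object of class `quartile_scheme`.
#' @export
quartile_scheme <- function(
    absolute = list(male = c(3.07, 3.75, 4.33),
                    female = c(2.14, 2.59, 2.93)),
    relative = list(male = c(37.5, 47.6, 54.8),
                    female = c(32.5, 40.2, 47.4))) {
  for (cuts in c(absolute, relative)) {
    if (length(cuts) != 3 || is.unsorted(cuts, strictly = TRUE)) {
      stop("quartile cut-points must be three strictly increasing values",
           call. = FALSE)
    }
  }
  structure(list(absolute = absolute, relative = relative),
            class = "quartile_scheme")
}

#' Assign fitness quartiles with sex-specific cut-points
#'
#' @param value VO2max values; L/min for `scale = "absolute"`, mL/kg/min for
#'   `"relative"`.
#' @param sex `"male"`/`"female"` per value.
#' @param scheme a [quartile_scheme()].
#' @param scale `"absolute"` or `"relative"`.
#' @return integer quartile 1-4 (1 = least fit); exhaustive and disjoint.
#' @export
assign_quartile <- function(value, sex, scheme = quartile_scheme(),
                            scale = c("absolute", "relative")) {
  scale <- match.arg(scale)
  cuts <- scheme[[scale]]
  q <- integer(length(value))
  for (s in c("male", "female")) {
    idx <- sex == s
    q[idx] <- 1L + findInterval(value[idx], cuts[[s]],
                                left.open = FALSE)
  }
  q
}

#' Agreement statistics stratified by sex, age band and fitness quartile
#'
#' Computes the overall [agreement_report()] and one report per stratum:
#' sex, age band (default <35, 35-49, 50-64, >=65 years), and sex-specific
#' quartiles of measured VO2max (absolute always; relative when body mass is
#' available). Strata with fewer than 2 pairs are reported with their count
#' and `NA` statistics.
#'
#' @param data a data frame with columns `measured`, `estimated`, `sex`,
#'   `age`, and optionally `body_mass` (kg).
#' @param scheme a [quartile_scheme()].
#' @param age_breaks interior age-band boundaries (years); a boundary age
#'   falls in the older band.
#' @return a tibble with `stratum`, `level` and the [agreement_report()]
#'   columns.
#' @export
stratified_report <- function(data, scheme = quartile_scheme(),
                              age_breaks = c(35, 50, 65)) {
  needed <- c("measured", "estimated", "sex", "age")
  miss <- setdiff(needed, names(data))
  if (length(miss) > 0) {
    stop("stratified_report: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  bands <- age_band_labels(age_breaks)
  data$age_band <- bands[1L + findInterval(data$age, age_breaks)]
  data$quartile_abs <- assign_quartile(data$measured, data$sex, scheme,
                                       "absolute")
  has_mass <- "body_mass" %in% names(data) && !anyNA(data$body_mass)
  if (has_mass) {
    rel <- data$measured * 1000 / data$body_mass
    data$quartile_rel <- assign_quartile(rel, data$sex, scheme, "relative")
  }

  one <- function(stratum, level, rows) {
    sub <- data[rows, ]
    if (nrow(sub) < 2) {
      rep <- agreement_report(c(1, 2), c(1, 2))  # template row
      rep[1, ] <- NA
      rep$n <- nrow(sub)
    } else {
      rep <- agreement_report(sub$measured, sub$estimated)
    }
    dplyr::bind_cols(tibble::tibble(stratum = stratum, level = level), rep)
  }

  out <- list(one("overall", "all", rep(TRUE, nrow(data))))
  for (s in sort(unique(data$sex))) {
    out[[length(out) + 1]] <- one("sex", s, data$sex == s)
  }
  for (b in bands) {
    out[[length(out) + 1]] <- one("age_band", b, data$age_band == b)
  }
  for (q in 1:4) {
    out[[length(out) + 1]] <- one("quartile_absolute", paste0("Q", q),
                                  data$quartile_abs == q)
  }
  if (has_mass) {
    for (q in 1:4) {
      out[[length(out) + 1]] <- one("quartile_relative", paste0("Q", q),
                                    data$quartile_rel == q)
    }
  }
  dplyr::bind_rows(out)
}

age_band_labels <- function(breaks) {
  b <- c(-Inf, breaks, Inf)
  vapply(seq_len(length(b) - 1), function(i) {
    lo <- b[i]; hi <- b[i + 1]
    if (is.infinite(lo)) paste0("<", hi)
    else if (is.infinite(hi)) paste0(">=", lo)
    else paste0(lo, "-", hi - 1)
  }, character(1))
}
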