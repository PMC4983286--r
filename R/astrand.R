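#' Load an Astrand nomogram table and its age-correction factors
#'
#' The Astrand single-stage method reads an uncorrected VO2max off a
#' sex-specific (work rate, heart rate) table and multiplies it by an
#' age-correction factor. The table shipped with the package is a synthetic
#' reconstruction generated from the nomogram's underlying linear
#' HR-%VO2max model (see the header of
#' `inst/extdata/astrand_table_synthetic.csv`), not a transcription of the
#' original published charts; users with access to the original tables can
#' supply their own files in the same long CSV format
#' (`sex, work_rate_w, hr_bpm, vo2max_l_min` and `age, factor`).
#'
#' @param nomogram_path path to a long-format nomogram CSV; default the
#'   shipped synthetic table.
#' @param correction_path path to an age-correction CSV; default the shipped
#'   standard factors.
#' @return an object of class `astrand_table`: a list with `nomogram` and
#'   `age_correction` tibbles.
#' @export
astrand_table <- function(nomogram_path = NULL, correction_path = NULL) {
  if (is.null(nomogram_path)) {
    nomogram_path <- system.file("extdata", "astrand_table_synthetic.csv",
                                 package = "ebtest")
  }
  if (is.null(correction_path)) {
    correction_path <- system.file("extdata", "astrand_age_correction.csv",
                                   package = "ebtest")
  }
  if (!file.exists(nomogram_path) || !file.exists(correction_path)) {
    stop("configuration error: Astrand table file(s) not found", call. = FALSE)
  }
  nomogram <- readr::read_csv(nomogram_path, comment = "#",
                              show_col_types = FALSE)
  needed <- c("sex", "work_rate_w", "hr_bpm", "vo2max_l_min")
  if (!all(needed %in% names(nomogram))) {
    stop("configuration error: nomogram CSV must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  correction <- readr::read_csv(correction_path, comment = "#",
                                show_col_types = FALSE)
  if (!all(c("age", "factor") %in% names(correction))) {
    stop("configuration error: correction CSV must have columns age, factor",
         call. = FALSE)
  }
  structure(list(nomogram = nomogram,
                 age_correction = correction[order(correction$age), ]),
            class = "astrand_table")
}

#' Estimate VO2max by the Astrand nomogram method
#'
#' Applies the high work rate and the steady-state heart rate at the high
#' work rate to the nomogram table (bilinear interpolation over work rate
#' and heart rate within the record's sex), then multiplies by the
#' age-correction factor (linear interpolation between tabulated ages).
#' The nomogram only applies to high-stage heart rates of 120-170 bpm;
#' records outside that window, outside the table's work-rate grid, or
#' outside the age-correction span are not applicable -- an error by
#' default, or `NA` with a reason under `on_invalid = "na"` (useful when
#' sweeping a cohort).
#'
#' @inheritParams eb_new_estimate
#' @param table an `astrand_table` from [astrand_table()].
#' @param on_invalid `"error"` (default) or `"na"`.
#' @return an estimate tibble (see [eb_new_estimate()]); non-applicable
#'   records under `"na"` carry `NA` estimates and a reason in `warnings`.
#' @export
astrand_estimate <- function(records, table = astrand_table(),
                             on_invalid = c("error", "na")) {
  on_invalid <- match.arg(on_invalid)
  if (!inherits(table, "astrand_table")) {
    stop("configuration error: `table` must be an astrand_table", call. = FALSE)
  }
  d <- derive_predictors(records)
  n <- nrow(d)
  vo2 <- rep(NA_real_, n)
  warn <- character(n)
  ages <- table$age_correction$age
  for (i in seq_len(n)) {
    reason <- applicability_reason(d$hr_high[i], d$age[i], d$po_high[i],
                                   d$sex[i], table)
    if (!is.na(reason)) {
      if (on_invalid == "error") {
        stop("not applicable (record ", d$id[i], "): ", reason, call. = FALSE)
      }
      warn[i] <- paste0("not applicable: ", reason)
      next
    }
    uncorrected <- bilinear_lookup(table$nomogram, d$sex[i],
                                   d$po_high[i], d$hr_high[i])
    factor <- stats::approx(ages, table$age_correction$factor,
                            xout = d$age[i], rule = 1)$y
    vo2[i] <- uncorrected * factor
  }
  make_estimate(d, "astrand", vo2, warn)
}

applicability_reason <- function(hr_high, age, po_high, sex, table) {
  if (hr_high < 120 || hr_high > 170) {
    return("heart rate at the high work rate outside the nomogram window 120-170 bpm")
  }
  grid <- table$nomogram[table$nomogram$sex == sex, ]
  if (nrow(grid) == 0) return(paste0("no nomogram values for sex '", sex, "'"))
  wr <- range(grid$work_rate_w)
  if (po_high < wr[1] || po_high > wr[2]) {
    return(sprintf("high work rate outside the table span %g-%g W",
                   wr[1], wr[2]))
  }
  ar <- range(table$age_correction$age)
  if (age < ar[1] || age > ar[2]) {
    return(sprintf("age outside the correction-factor span %g-%g years",
                   ar[1], ar[2]))
  }
  NA_character_
}

# bilinear interpolation on the (work rate, HR) grid for one sex;
# exact at grid nodes by construction
bilinear_lookup <- function(nomogram, sex, po, hr) {
  grid <- nomogram[nomogram$sex == sex, ]
  ws <- sort(unique(grid$work_rate_w))
  hs <- sort(unique(grid$hr_bpm))
  w_lo <- max(ws[ws <= po]); w_hi <- min(ws[ws >= po])
  h_lo <- max(hs[hs <= hr]); h_hi <- min(hs[hs >= hr])
  val <- function(w, h) {
    grid$vo2max_l_min[grid$work_rate_w == w & grid$hr_bpm == h]
  }
  tw <- if (w_hi == w_lo) 0 else (po - w_lo) / (w_hi - w_lo)
  th <- if (h_hi == h_lo) 0 else (hr - h_lo) / (h_hi - h_lo)
  (1 - tw) * (1 - th) * val(w_lo, h_lo) +
    tw * (1 - th) * val(w_hi, h_lo) +
    (1 - tw) * th * val(w_lo, h_hi) +
    tw * th * val(w_hi, h_hi)
}
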