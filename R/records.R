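#' Build and validate a table of submaximal test records
#'
#' Normalises a data frame of per-participant test inputs into the record
#' layout used throughout the package and checks the protocol invariants:
#' `po_high > po_standard`, `hr_high > hr_standard`, `hr_standard > 0`, and
#' positive body mass where given. Ages outside 20-86 years (the span the
#' prediction equations were developed on) produce a warning, not a
#' rejection. Rows that fail a hard invariant are dropped (or raise an
#' error, see `on_invalid`); the dropped rows and reasons are attached as
#' the `"problems"` attribute.
#'
#' @param data a data frame with columns `sex` ("male"/"female", or "M"/"F"),
#'   `age` (years), `po_standard` and `po_high` (W), `hr_standard` and
#'   `hr_high` (bpm); optionally `id`, `body_mass` (kg) and
#'   `measured_vo2max` (L/min).
#' @param on_invalid `"drop"` (default) keeps valid rows and reports the
#'   rest in the `"problems"` attribute; `"error"` fails on the first
#'   invalid row.
#' @return a tibble of validated records with a `"problems"` attribute
#'   (tibble of `row`, `id`, `problem`).
#' @export
test_records <- function(data, on_invalid = c("drop", "error")) {
  on_invalid <- match.arg(on_invalid)
  data <- tibble::as_tibble(data)
  required <- c("sex", "age", "po_standard", "po_high",
                "hr_standard", "hr_high")
  miss <- setdiff(required, names(data))
  if (length(miss) > 0) {
    stop("format error: missing required column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"id" %in% names(data)) data$id <- as.character(seq_len(nrow(data)))
  data$id <- as.character(data$id)
  if (!"body_mass" %in% names(data)) data$body_mass <- NA_real_
  if (!"measured_vo2max" %in% names(data)) data$measured_vo2max <- NA_real_
  data$sex <- normalize_sex(data$sex)

  probs <- character(nrow(data))
  bad <- function(cond, msg) {
    cond[is.na(cond)] <- TRUE
    probs[cond] <<- ifelse(probs[cond] == "", msg,
                           paste(probs[cond], msg, sep = "; "))
  }
  bad(is.na(data$sex), "sex not one of male/female")
  bad(!(data$po_high > data$po_standard), "po_high must exceed po_standard")
  bad(!(data$hr_high > data$hr_standard), "hr_high must exceed hr_standard")
  bad(!(data$hr_standard > 0), "hr_standard must be positive")
  bad(!is.na(data$body_mass) & data$body_mass <= 0,
      "body_mass must be positive")
  bad(!is.na(data$measured_vo2max) & data$measured_vo2max <= 0,
      "measured_vo2max must be positive")

  invalid <- probs != ""
  if (any(invalid) && on_invalid == "error") {
    stop("invalid record (row ", which(invalid)[1], "): ",
         probs[which(invalid)[1]], call. = FALSE)
  }
  out_of_span <- !invalid & !is.na(data$age) &
    (data$age < 20 | data$age > 86)
  if (any(out_of_span)) {
    warning(sum(out_of_span),
            " record(s) with age outside 20-86 years; the prediction ",
            "equations are extrapolating there", call. = FALSE)
  }
  problems <- tibble::tibble(row = which(invalid),
                             id = data$id[invalid],
                             problem = probs[invalid])
  keep <- data[!invalid,
               c("id", "sex", "age", "body_mass", "po_standard", "po_high",
                 "hr_standard", "hr_high", "measured_vo2max",
                 setdiff(names(data),
                         c("id", "sex", "age", "body_mass", "po_standard",
                           "po_high", "hr_standard", "hr_high",
                           "measured_vo2max")))]
  attr(keep, "problems") <- problems
  keep
}

normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("m", "male", "man", "men", "1")] <- "male"
  out[x %in% c("f", "female", "woman", "women", "0")] <- "female"
  out
}

#' Derive the heart-rate/power predictors of the prediction equations
#'
#' Adds the three derived predictors to a record table: `delta_hr`
#' (`hr_high - hr_standard`, bpm), `delta_po` (`po_high - po_standard`, W)
#' and `hr_per_po` (their ratio, bpm/W) -- the increase in steady-state
#' heart rate per unit increase in power output between the two stages.
#'
#' @param records a record table from [test_records()] (or any data frame
#'   with the power and heart-rate columns).
#' @return the input with `delta_hr`, `delta_po`, `hr_per_po` columns added.
#' @export
derive_predictors <- function(records) {
  delta_hr <- records$hr_high - records$hr_standard
  delta_po <- records$po_high - records$po_standard
  if (any(delta_po <= 0, na.rm = TRUE)) {
    stop("invalid test: delta_po must be positive for every record",
         call. = FALSE)
  }
  if (any(delta_hr <= 0, na.rm = TRUE)) {
    stop("invalid test: delta_hr must be positive for every record",
         call. = FALSE)
  }
  records$delta_hr <- delta_hr
  records$delta_po <- delta_po
  records$hr_per_po <- delta_hr / delta_po
  records
}
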