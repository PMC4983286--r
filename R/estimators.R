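# Published prediction-equation coefficients, stored exactly as printed
# (5 decimals); never re-rounded.
.eb_new_coef <- list(
  male = c(intercept = 2.04900, age = -0.00858, hr_per_po = -0.90742,
           delta_po = 0.00178, hr_standard = -0.00290),
  female = c(intercept = 1.84390, age = -0.00673, hr_per_po = -0.62578,
             delta_po = 0.00175, hr_standard = -0.00471)
)
.eb_2012_coef <- c(intercept = 4.98196, hr_per_po = -2.88618,
                   sex_male = 0.65015, age = -0.01712)

# Development-range gates. The sex-specific equations were developed on
# ages 20-86 and absolute VO2max 1.33-3.94 L/min (women) / 1.67-5.97 (men);
# the 2012 pooled equation on ages 21-65 and 1.56-3.73 / 2.75-4.49 L/min.
.eb_new_range <- list(age = c(20, 86),
                      vo2max = list(male = c(1.67, 5.97),
                                    female = c(1.33, 3.94)))
.eb_2012_range <- list(age = c(21, 65),
                       vo2max = list(male = c(2.75, 4.49),
                                     female = c(1.56, 3.73)))

#' Published coefficients of the prediction equations
#'
#' @return a list with elements `eb_new` (per-sex named coefficient vectors
#'   of the log-linear equations: intercept, age, hr_per_po, delta_po,
#'   hr_standard) and `eb_2012` (the pooled linear equation: intercept,
#'   hr_per_po, sex_male, age).
#' @export
eb_coefficients <- function() {
  list(eb_new = .eb_new_coef, eb_2012 = .eb_2012_coef)
}

#' Estimate VO2max with the sex-specific log-linear equations
#'
#' Evaluates, per record, the sex-specific equation
#' \deqn{\ln \mathrm{VO_2max} = b_0 + b_1\,\mathrm{age}
#'   + b_2\,\Delta HR/\Delta PO + b_3\,\Delta PO + b_4\,HR_{std}}
#' and exponentiates. Age in years, \eqn{\Delta PO} in watts,
#' \eqn{\Delta HR/\Delta PO} in bpm/W, heart rate at the standard work rate
#' in bpm. Estimates are flagged (`in_valid_range = FALSE`, with a warning
#' string) when age falls outside 20-86 years or the predicted value falls
#' outside the development range (1.33-3.94 L/min for women, 1.67-5.97 for
#' men); out-of-range use is advisory, never an error.
#'
#' @param records a record table (see [test_records()]).
#' @return an estimate tibble: `id`, `method`, `vo2max_abs` (L/min),
#'   `vo2max_rel` (mL/kg/min, `NA` without body mass), `in_valid_range`,
#'   `warnings` (semicolon-joined, `""` when none).
#' @examples
#' r <- tibble::tibble(sex = "male", age = 40, po_standard = 30,
#'                     po_high = 150, hr_standard = 90, hr_high = 150)
#' eb_new_estimate(test_records(r))
#' @export
eb_new_estimate <- function(records) {
  d <- derive_predictors(records)
  coefs <- .eb_new_coef
  lp <- ifelse(d$sex == "male",
               coefs$male["intercept"] + coefs$male["age"] * d$age +
                 coefs$male["hr_per_po"] * d$hr_per_po +
                 coefs$male["delta_po"] * d$delta_po +
                 coefs$male["hr_standard"] * d$hr_standard,
               coefs$female["intercept"] + coefs$female["age"] * d$age +
                 coefs$female["hr_per_po"] * d$hr_per_po +
                 coefs$female["delta_po"] * d$delta_po +
                 coefs$female["hr_standard"] * d$hr_standard)
  vo2 <- exp(lp)
  warn <- range_warnings(d$age, vo2, d$sex, .eb_new_range)
  make_estimate(d, "eb-new", vo2, warn)
}

#' Estimate VO2max with the original 2012 pooled linear equation
#'
#' Evaluates \deqn{\mathrm{VO_2max} = 4.98196 - 2.88618\,\Delta HR/\Delta PO
#'   + 0.65015\,\mathrm{sex} - 0.01712\,\mathrm{age}} with sex coded
#' women = 0, men = 1 (an internal detail; records carry an explicit sex
#' label). The linear form is unbounded below, so implausible inputs can
#' drive the estimate to or below zero; such estimates, and ages outside
#' 21-65 or predictions outside the 2012 development range (1.56-3.73 L/min
#' women, 2.75-4.49 men), carry warnings and `in_valid_range = FALSE`.
#'
#' @inheritParams eb_new_estimate
#' @return an estimate tibble (see [eb_new_estimate()]).
#' @export
eb_2012_estimate <- function(records) {
  d <- derive_predictors(records)
  b <- .eb_2012_coef
  vo2 <- b["intercept"] + b["hr_per_po"] * d$hr_per_po +
    b["sex_male"] * (d$sex == "male") + b["age"] * d$age
  vo2 <- unname(vo2)
  warn <- range_warnings(d$age, vo2, d$sex, .eb_2012_range)
  nonpos <- vo2 <= 0
  warn[nonpos] <- paste_warn(warn[nonpos],
                             "non-positive estimate from the linear form")
  make_estimate(d, "eb-2012", vo2, warn)
}

range_warnings <- function(age, vo2, sex, range) {
  warn <- character(length(age))
  out_age <- age < range$age[1] | age > range$age[2]
  warn[out_age] <- paste_warn(warn[out_age], sprintf(
    "age outside development range %g-%g years",
    range$age[1], range$age[2]))
  lo <- ifelse(sex == "male", range$vo2max$male[1], range$vo2max$female[1])
  hi <- ifelse(sex == "male", range$vo2max$male[2], range$vo2max$female[2])
  out_vo2 <- vo2 < lo | vo2 > hi
  warn[out_vo2] <- paste_warn(warn[out_vo2], sprintf(
    "predicted VO2max outside development range %g-%g L/min",
    lo[out_vo2], hi[out_vo2]))
  warn
}

paste_warn <- function(existing, msg) {
  ifelse(existing == "", msg, paste(existing, msg, sep = "; "))
}

make_estimate <- function(d, method, vo2, warn) {
  tibble::tibble(
    id = d$id,
    method = method,
    vo2max_abs = vo2,
    vo2max_rel = ifelse(is.na(d$body_mass), NA_real_,
                        vo2 * 1000 / d$body_mass),
    in_valid_range = warn == "",
    warnings = warn
  )
}

#' Estimate VO2max by one or all methods
#'
#' Convenience dispatcher over [eb_new_estimate()], [eb_2012_estimate()] and
#' [astrand_estimate()].
#'
#' @inheritParams eb_new_estimate
#' @param method one of `"eb-new"`, `"eb-2012"`, `"astrand"`, `"all"`.
#' @param table an Astrand table (see [astrand_table()]); loaded from the
#'   shipped files when the Astrand method is requested and none is given.
#' @param on_invalid for the Astrand method: `"error"` (default) or `"na"`
#'   for records outside the nomogram's applicability window.
#' @return an estimate tibble, row-bound across methods for `"all"`.
#' @export
estimate_vo2max <- function(records,
                            method = c("eb-new", "eb-2012", "astrand", "all"),
                            table = NULL, on_invalid = "error") {
  method <- match.arg(method)
  pieces <- list()
  if (method %in% c("eb-new", "all")) {
    pieces$new <- eb_new_estimate(records)
  }
  if (method %in% c("eb-2012", "all")) {
    pieces$old <- eb_2012_estimate(records)
  }
  if (method %in% c("astrand", "all")) {
    if (is.null(table)) table <- astrand_table()
    inv <- if (method == "all") "na" else on_invalid
    pieces$astrand <- astrand_estimate(records, table, on_invalid = inv)
  }
  dplyr::bind_rows(pieces)
}

#' 95% prediction half-width from a coefficient of variation
#'
#' With a validation coefficient of variation `cv_fraction` (as a fraction,
#' e.g. 0.084 for 8.4%), 95 of 100 individuals with true VO2max `vo2max`
#' are predicted within `1.96 * cv_fraction * vo2max` of it. With the
#' model-group CVs (8.4% men, 9.2% women), a man with a true VO2max of
#' 3.0 L/min is predicted within about 0.49 L/min and a woman within about
#' 0.54 L/min.
#'
#' @param cv_fraction coefficient of variation as a fraction, > 0.
#' @param vo2max true/reference VO2max in L/min, >= 0.
#' @return half-width of the 95% prediction band, L/min.
#' @export
prediction_halfwidth <- function(cv_fraction, vo2max) {
  if (any(cv_fraction <= 0, na.rm = TRUE)) {
    stop("invalid argument: cv_fraction must be positive", call. = FALSE)
  }
  if (any(vo2max < 0, na.rm = TRUE)) {
    stop("invalid argument: vo2max must be non-negative", call. = FALSE)
  }
  1.96 * cv_fraction * vo2max
}
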