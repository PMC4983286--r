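# Sign convention used everywhere: difference = estimated - measured, so an
# overestimate is positive. This reconciles the stratified tables (an
# underestimation of fit individuals prints as a negative difference).
.diff_sign <- "estimated_minus_measured"

agreement_differences <- function(measured, estimated) {
  check_paired(measured, estimated, min_n = 1)
  estimated - measured
}

check_paired <- function(measured, estimated, min_n = 2) {
  if (length(measured) != length(estimated)) {
    stop("paired sample: measured and estimated must have equal length",
         call. = FALSE)
  }
  if (length(measured) < min_n) {
    stop("insufficient data: need at least ", min_n, " pairs", call. = FALSE)
  }
  if (anyNA(measured) || anyNA(estimated)) {
    stop("paired sample: NA values not allowed; filter first", call. = FALSE)
  }
  invisible(TRUE)
}

#' Coefficient of variation between measured and estimated values
#'
#' The SD of the per-pair differences divided by the mean level of the two
#' series, as a percentage:
#' `100 * SD(estimated - measured) / ((mean(measured) + mean(estimated)) / 2)`.
#' The sample SD (n-1 denominator) is the default; the denominator is the
#' mean of the two group means (the grand mean of all values), the standard
#' method-comparison reading.
#'
#' @param measured,estimated paired VO2max vectors (L/min), n >= 2.
#' @param sd_type `"sample"` (n-1, default) or `"population"` (n).
#' @return the coefficient of variation in percent.
#' @export
cv_percent <- function(measured, estimated,
                       sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  check_paired(measured, estimated)
  d <- agreement_differences(measured, estimated)
  s <- stats::sd(d)
  if (sd_type == "population") {
    s <- s * sqrt((length(d) - 1) / length(d))
  }
  level <- (mean(measured) + mean(estimated)) / 2
  100 * s / level
}

#' SEE and adjusted R-squared of measured on estimated
#'
#' Ordinary least squares with measured VO2max as the response and the
#' estimated value as the single predictor. The standard error of the
#' estimate (SEE) is the residual standard error; R-squared carries the
#' usual one-predictor adjustment. Note this measures linear association,
#' not identity: `measured = 2 * estimated` fits perfectly.
#'
#' @inheritParams cv_percent
#' @return a list with `see` (L/min) and `r2_adjusted`.
#' @export
see_and_r2 <- function(measured, estimated) {
  check_paired(measured, estimated, min_n = 3)
  if (stats::var(estimated) == 0) {
    stop("degenerate regression: estimated values are constant", call. = FALSE)
  }
  fit <- stats::lm(measured ~ estimated)
  s <- summary(fit)
  list(see = s$sigma, r2_adjusted = s$adj.r.squared)
}

#' Bland-Altman mean difference and limits of agreement
#'
#' Mean difference (estimated - measured) with limits of agreement at
#' `mean +/- 1.96 * SD` of the differences (sample SD), plus the per-pair
#' plot coordinates (mean of each pair on x, difference on y).
#'
#' @inheritParams cv_percent
#' @return a list: `mean_diff`, `loa_lower`, `loa_upper` (L/min) and
#'   `points`, a tibble of `mean` and `diff` per pair.
#' @export
bland_altman <- function(measured, estimated) {
  check_paired(measured, estimated)
  d <- agreement_differences(measured, estimated)
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m,
       loa_lower = m - 1.96 * s,
       loa_upper = m + 1.96 * s,
       points = tibble::tibble(mean = (measured + estimated) / 2, diff = d))
}

#' Paired t-test of estimated against measured
#'
#' Two-sided paired t-test on the differences (estimated - measured), with
#' the t-based 95% confidence interval (n-1 df). Zero-variance differences
#' are degenerate for the t statistic: identical vectors return p = 1, a
#' constant nonzero difference returns p = 0, both with a note.
#'
#' @inheritParams cv_percent
#' @param conf_level confidence level for the interval (default 0.95).
#' @return a list: `mean_diff`, `ci_lower`, `ci_upper`, `p_value`, `note`.
#' @export
paired_t <- function(measured, estimated, conf_level = 0.95) {
  check_paired(measured, estimated)
  d <- agreement_differences(measured, estimated)
  if (stats::sd(d) == 0) {
    m <- mean(d)
    return(list(mean_diff = m, ci_lower = m, ci_upper = m,
                p_value = if (m == 0) 1 else 0,
                note = "zero-variance differences; t statistic degenerate"))
  }
  tt <- stats::t.test(estimated, measured, paired = TRUE,
                      conf.level = conf_level)
  list(mean_diff = unname(tt$estimate), ci_lower = tt$conf.int[1],
       ci_upper = tt$conf.int[2], p_value = tt$p.value, note = NA_character_)
}

#' Spearman correlation of the estimation error with the measured level
#'
#' Rank correlation between the differences (estimated - measured) and the
#' measured VO2max, with average ranks for ties. A negative rho means the
#' method overestimates low-fitness and underestimates high-fitness
#' individuals. Constant differences make the correlation undefined; `NA`
#' with a note is returned.
#'
#' @inheritParams cv_percent
#' @return a list: `rho`, `p_value`, `note`.
#' @export
error_vs_level <- function(measured, estimated) {
  check_paired(measured, estimated, min_n = 3)
  d <- agreement_differences(measured, estimated)
  if (stats::sd(d) == 0 || stats::sd(measured) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_,
                note = "constant differences or levels; rank correlation undefined"))
  }
  ct <- suppressWarnings(
    stats::cor.test(d, measured, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, note = NA_character_)
}

#' Full agreement report for one estimator against measured values
#'
#' Bundles every validation statistic reported for a method-comparison
#' sample: mean difference (estimated - measured) with 95% CI and paired-t
#' p-value, coefficient of variation, adjusted R-squared and SEE from the
#' regression of measured on estimated, Bland-Altman limits of agreement,
#' and the Spearman correlation of error with measured level.
#'
#' @inheritParams cv_percent
#' @return a one-row tibble: `n`, `mean_measured`, `sd_measured`,
#'   `mean_estimated`, `sd_estimated`, `mean_diff`, `ci_lower`, `ci_upper`,
#'   `p_value`, `cv_percent`, `r2_adjusted`, `see`, `loa_lower`,
#'   `loa_upper`, `rho`, `rho_p`.
#' @export
agreement_report <- function(measured, estimated) {
  check_paired(measured, estimated)
  t_part <- paired_t(measured, estimated)
  ba <- bland_altman(measured, estimated)
  reg <- if (length(measured) >= 3 && stats::var(estimated) > 0) {
    see_and_r2(measured, estimated)
  } else {
    list(see = NA_real_, r2_adjusted = NA_real_)
  }
  sp <- if (length(measured) >= 3) {
    error_vs_level(measured, estimated)
  } else {
    list(rho = NA_real_, p_value = NA_real_)
  }
  tibble::tibble(
    n = length(measured),
    mean_measured = mean(measured), sd_measured = stats::sd(measured),
    mean_estimated = mean(estimated), sd_estimated = stats::sd(estimated),
    mean_diff = t_part$mean_diff,
    ci_lower = t_part$ci_lower, ci_upper = t_part$ci_upper,
    p_value = t_part$p_value,
    cv_percent = cv_percent(measured, estimated),
    r2_adjusted = reg$r2_adjusted, see = reg$see,
    loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
    rho = sp$rho, rho_p = sp$p_value
  )
}
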