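#' Forward stepwise OLS with F-to-enter / F-to-remove probabilities
#'
#' Classical forward selection: at each step the candidate whose partial F
#' (given the variables already in the model) has the smallest p-value
#' enters if that p-value is below `p_enter`; after each entry, any included
#' variable whose partial p-value exceeds `p_remove` is removed. The loop
#' terminates when no entry or removal occurs. The partial F of a single
#' added variable equals the square of its t statistic, so the entry
#' p-value is computed from the t test of the candidate's coefficient in
#' the trial fit.
#'
#' @param data a data frame containing `response` and `candidates`.
#' @param response name of the response column.
#' @param candidates character vector of candidate predictor columns.
#' @param p_enter probability of F for entry (default 0.05).
#' @param p_remove probability of F for removal (default 0.10); must satisfy
#'   `0 < p_enter <= p_remove < 1`.
#' @return an object of class `eb_model_fit`: a list with `coefficients`
#'   (tibble of term, estimate, ci_lower, ci_upper, p_value), `entry_order`,
#'   `tolerances`, `r2_adjusted`, `sigma` (residual SD), `n`, `response`,
#'   and the underlying `lm` fit.
#' @export
forward_select <- function(data, response, candidates,
                           p_enter = 0.05, p_remove = 0.10) {
  stopifnot(p_enter > 0, p_enter <= p_remove, p_remove <= 1)
  miss <- setdiff(c(response, candidates), names(data))
  if (length(miss) > 0) {
    stop("forward_select: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) <= length(candidates) + 2) {
    stop("forward_select: need n > number of candidates + 2", call. = FALSE)
  }
  included <- character(0)
  remaining <- candidates
  steps <- 0L
  repeat {
    steps <- steps + 1L
    if (steps > 10L * length(candidates) + 10L) {
      warning("forward_select: entry/removal cycling detected; stopping",
              call. = FALSE)
      break
    }
    changed <- FALSE
    if (length(remaining) > 0) {
      entry_p <- vapply(remaining, function(cand) {
        trial <- fit_ols(data, response, c(included, cand))
        co <- summary(trial)$coefficients
        if (!cand %in% rownames(co)) {
          stop("degenerate design: candidate '", cand,
               "' is collinear with {",
               paste(c("(Intercept)", included), collapse = ", "), "}",
               call. = FALSE)
        }
        co[cand, "Pr(>|t|)"]
      }, numeric(1))
      best <- names(which.min(entry_p))
      if (entry_p[best] < p_enter) {
        included <- c(included, best)
        remaining <- setdiff(remaining, best)
        changed <- TRUE
      }
    }
    if (length(included) > 0) {
      fit <- fit_ols(data, response, included)
      pv <- summary(fit)$coefficients[included, "Pr(>|t|)", drop = TRUE]
      worst <- included[which.max(pv)]
      if (max(pv) > p_remove) {
        remaining <- c(remaining, worst)
        included <- setdiff(included, worst)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  build_model_fit(data, response, included, entry_order = included)
}

fit_ols <- function(data, response, terms) {
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  stats::lm(stats::as.formula(paste(response, "~", rhs)), data = data)
}

build_model_fit <- function(data, response, included, entry_order) {
  fit <- fit_ols(data, response, included)
  s <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  co <- s$coefficients
  coefficients <- tibble::tibble(
    term = rownames(co),
    estimate = unname(co[, "Estimate"]),
    ci_lower = unname(ci[, 1]),
    ci_upper = unname(ci[, 2]),
    p_value = unname(co[, "Pr(>|t|)"])
  )
  tol <- if (length(included) >= 2) {
    tolerance_check(data[, included, drop = FALSE])$tolerance
  } else if (length(included) == 1) {
    stats::setNames(1, included)
  } else {
    numeric(0)
  }
  structure(list(coefficients = coefficients,
                 entry_order = entry_order,
                 tolerances = tol,
                 r2_adjusted = s$adj.r.squared,
                 sigma = s$sigma,
                 n = nrow(data),
                 response = response,
                 fit = fit),
            class = "eb_model_fit")
}

#' @export
print.eb_model_fit <- function(x, ...) {
  cat("Forward-selection OLS fit of", x$response,
      "(n =", x$n, ")\n")
  cat("Entry order:", if (length(x$entry_order) == 0) "(none entered)"
      else paste(x$entry_order, collapse = " -> "), "\n")
  print(as.data.frame(x$coefficients), row.names = FALSE)
  cat(sprintf("Adjusted R-squared %.4f, residual SD %.5f\n",
              x$r2_adjusted, x$sigma))
  if (length(x$tolerances) > 0) {
    cat("Tolerances:",
        paste(sprintf("%s %.3f", names(x$tolerances), x$tolerances),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Refit the log-linear prediction model on a cohort
#'
#' Runs [forward_select()] of `ln(measured_vo2max)` on the four candidate
#' predictors of the published equations -- age, `hr_per_po`
#' (delta HR / delta PO), `delta_po` and `hr_standard` -- within one sex.
#' This reproduces the model-development procedure; it never replaces the
#' shipped published coefficients, which [eb_new_estimate()] uses verbatim.
#'
#' @param cohort a record table with `measured_vo2max` (see
#'   [generate_cohort()] or [read_records()]).
#' @param sex `"male"` or `"female"`; rows of the other sex are dropped.
#' @param p_enter,p_remove see [forward_select()].
#' @return an `eb_model_fit`.
#' @export
fit_eb_model <- function(cohort, sex = c("male", "female"),
                         p_enter = 0.05, p_remove = 0.10) {
  sex <- match.arg(sex)
  d <- derive_predictors(cohort[cohort$sex == sex, ])
  if (any(is.na(d$measured_vo2max)) || any(d$measured_vo2max <= 0)) {
    stop("fit_eb_model: every record needs a positive measured_vo2max",
         call. = FALSE)
  }
  d$ln_vo2max <- log(d$measured_vo2max)
  forward_select(d, "ln_vo2max",
                 c("age", "hr_per_po", "delta_po", "hr_standard"),
                 p_enter = p_enter, p_remove = p_remove)
}

#' Screen for sex interactions in the pooled log-linear model
#'
#' Fits the pooled two-sex model of `ln(measured_vo2max)` on age,
#' `hr_per_po`, `delta_po`, `hr_standard` and sex, plus the
#' sex-by-`hr_standard` and sex-by-`hr_per_po` interaction terms, and
#' reports the interaction p-values. When either is below `p_threshold` the
#' recommendation is to fit the sexes separately.
#'
#' @param cohort a record table with both sexes and `measured_vo2max`;
#'   n >= 20.
#' @param p_threshold significance threshold for the split recommendation.
#' @return a list: `p_values` (named, `sex:hr_standard` and
#'   `sex:hr_per_po`), `recommendation` (`"split"` or `"pooled"`), `fit`.
#' @export
interaction_screen <- function(cohort, p_threshold = 0.05) {
  d <- derive_predictors(cohort)
  if (length(unique(d$sex)) < 2) {
    stop("not applicable: interaction screening needs both sexes",
         call. = FALSE)
  }
  if (nrow(d) < 20) {
    stop("interaction_screen: need n >= 20", call. = FALSE)
  }
  d$ln_vo2max <- log(d$measured_vo2max)
  d$sex_male <- as.numeric(d$sex == "male")
  fit <- stats::lm(ln_vo2max ~ age + hr_per_po + delta_po + hr_standard +
                     sex_male + sex_male:hr_standard + sex_male:hr_per_po,
                   data = d)
  co <- summary(fit)$coefficients
  p <- c("sex:hr_standard" = co["hr_standard:sex_male", "Pr(>|t|)"],
         "sex:hr_per_po" = co["hr_per_po:sex_male", "Pr(>|t|)"])
  list(p_values = p,
       recommendation = if (any(p < p_threshold)) "split" else "pooled",
       fit = fit)
}

#' Tolerance collinearity diagnostic
#'
#' Tolerance of a predictor is 1 minus the R-squared of its OLS regression
#' on the other predictors (the reciprocal of the variance inflation
#' factor). Values at or below 0.2 are flagged as likely multicollinearity.
#'
#' @param x a data frame or matrix of predictor columns (>= 2 columns), or
#'   an `eb_model_fit` (its included predictors are extracted from the
#'   training data stored in the `lm` fit).
#' @param flag_at tolerance threshold for flagging (default 0.2).
#' @return a list: `tolerance` (named numeric) and `flagged` (character).
#' @export
tolerance_check <- function(x, flag_at = 0.2) {
  if (inherits(x, "eb_model_fit")) {
    terms <- setdiff(x$coefficients$term, "(Intercept)")
    x <- stats::model.matrix(x$fit)[, terms, drop = FALSE]
  }
  x <- as.matrix(as.data.frame(x))
  if (ncol(x) < 2) {
    stop("tolerance_check: need at least 2 predictors", call. = FALSE)
  }
  tol <- vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    res <- fit$residuals
    tss <- sum((x[, j] - mean(x[, j]))^2)
    if (tss == 0) return(0)
    max(0, sum(res^2) / tss)
  }, numeric(1))
  names(tol) <- colnames(x)
  list(tolerance = tol, flagged = names(tol)[tol <= flag_at])
}
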