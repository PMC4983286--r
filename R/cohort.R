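#' Specify a synthetic test cohort
#'
#' Parameters of the synthetic-cohort generator. The defaults reproduce the
#' marginal structure of the published model group: 117 men and 100 women;
#' age 48.3 +/- 15.7 (men) and 46.1 +/- 16.8 (women) years truncated to
#' 20-86; body mass 80.7 +/- 9.0 and 63.7 +/- 8.5 kg; VO2max 3.73 +/- 0.86
#' and 2.55 +/- 0.58 L/min truncated to the model-group ranges (1.67-5.97
#' men, 1.33-3.94 women). Two modes:
#' \describe{
#'   \item{`exact_model`}{covariates drawn uniformly over the design space
#'     (age over `age_range`; delta HR / delta PO 0.25-1.0 bpm/W; delta PO
#'     60-220 W; HR at the standard stage 70-115 bpm) and ln VO2max set
#'     exactly from the published sex equation plus Gaussian noise of SD
#'     `ln_noise_sd`; used for coefficient-recovery and calibration tests.}
#'   \item{`physiologic`}{age, mass and VO2max drawn from the truncated
#'     normals above; maximal HR from `hrmax_intercept + hrmax_slope * age`
#'     plus Gaussian SD `hrmax_sd`; an individual linear HR-VO2 line through
#'     (resting VO2, resting HR) and (VO2max, HRmax); the high work rate
#'     chosen to target `target_hrmax_frac` of maximal HR (a stand-in for
#'     the protocol's "perceived exertion of about 14"); stage HRs read off
#'     the line with bpm-level noise; invariants enforced by rejection
#'     sampling (at most 1000 attempts per record).}
#' }
#' The default ln-scale noise SD of 0.085 is a calibration chosen so that
#' end-to-end validation of the sex-specific equations on an exact-model
#' cohort yields a coefficient of variation of about 8-9%.
#'
#' @param n_male,n_female records per sex.
#' @param mode `"exact_model"` or `"physiologic"`.
#' @param ln_noise_sd SD of Gaussian noise added to ln VO2max in
#'   `exact_model` mode (0 = noise-free).
#' @param age_mean,age_sd,age_range age distribution (years), per sex where
#'   named.
#' @param mass_mean,mass_sd body-mass distribution (kg) per sex.
#' @param vo2max_mean,vo2max_sd,vo2max_range VO2max distribution (L/min)
#'   per sex.
#' @param hrmax_intercept,hrmax_slope,hrmax_sd age-predicted maximal HR
#'   model (bpm); the default 208 - 0.7 x age is a standard published
#'   estimator.
#' @param hr_rest_mean,hr_rest_sd resting HR (bpm); no published cohort
#'   value exists, a configurable default.
#' @param hr_noise_sd bpm-level noise on stage heart rates in physiologic
#'   mode.
#' @param target_hrmax_frac fraction of maximal HR targeted by the high
#'   work rate in physiologic mode.
#' @param po_standard the standard stage work rate (W); 0.5 kp at 60 rpm.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_male = 117, n_female = 100,
                        mode = c("exact_model", "physiologic"),
                        ln_noise_sd = 0.085,
                        age_mean = c(male = 48.3, female = 46.1),
                        age_sd = c(male = 15.7, female = 16.8),
                        age_range = c(20, 86),
                        mass_mean = c(male = 80.7, female = 63.7),
                        mass_sd = c(male = 9.0, female = 8.5),
                        vo2max_mean = c(male = 3.73, female = 2.55),
                        vo2max_sd = c(male = 0.86, female = 0.58),
                        vo2max_range = list(male = c(1.67, 5.97),
                                            female = c(1.33, 3.94)),
                        hrmax_intercept = 208, hrmax_slope = -0.7,
                        hrmax_sd = 8,
                        hr_rest_mean = 65, hr_rest_sd = 8,
                        hr_noise_sd = 2,
                        target_hrmax_frac = 0.75,
                        po_standard = kp_rpm_to_watts(0.5, 60)) {
  mode <- match.arg(mode)
  stopifnot(n_male >= 0, n_female >= 0, ln_noise_sd >= 0,
            all(age_sd > 0), all(mass_sd > 0), all(vo2max_sd > 0),
            hrmax_sd > 0, hr_rest_sd > 0, hr_noise_sd >= 0,
            target_hrmax_frac > 0, target_hrmax_frac < 1,
            age_range[1] < age_range[2])
  for (s in c("male", "female")) {
    check_feasible(age_mean[[s]], age_sd[[s]], age_range, paste(s, "age"))
    check_feasible(vo2max_mean[[s]], vo2max_sd[[s]], vo2max_range[[s]],
                   paste(s, "VO2max"))
    if (vo2max_range[[s]][1] >= vo2max_range[[s]][2]) {
      stop("spec error: VO2max truncation bounds must be ordered",
           call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "cohort_spec")
}

check_feasible <- function(mean, sd, range, what) {
  if (range[1] > mean + 4 * sd || range[2] < mean - 4 * sd) {
    stop("spec error: truncation bounds for ", what,
         " exclude mean +/- 4 SD", call. = FALSE)
  }
}

# truncated-normal draws via inverse-CDF (deterministic given the RNG stream)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Generate a synthetic cohort of test records
#'
#' Draws a cohort according to `spec` (see [cohort_spec()]). The same spec
#' and seed always produce the identical cohort. Every emitted record
#' satisfies the protocol invariants (`po_high > po_standard`,
#' `hr_high > hr_standard`).
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return a record tibble (as from [test_records()]) with an extra
#'   `true_vo2max` column: the generative VO2max before measurement noise
#'   (`exact_model`) or the drawn maximal value (`physiologic`);
#'   `measured_vo2max` plays the role of the maximal-test measurement.
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  parts <- list()
  for (s in c("male", "female")) {
    n <- if (s == "male") spec$n_male else spec$n_female
    if (n == 0) next
    parts[[s]] <- if (spec$mode == "exact_model") {
      generate_exact(spec, s, n)
    } else {
      generate_physiologic(spec, s, n)
    }
  }
  out <- dplyr::bind_rows(parts)
  out$id <- sprintf("S%04d", seq_len(nrow(out)))
  out[, c("id", setdiff(names(out), "id"))]
}

generate_exact <- function(spec, s, n) {
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  hr_per_po <- stats::runif(n, 0.25, 1.0)
  delta_po <- stats::runif(n, 60, 220)
  hr_standard <- stats::runif(n, 70, 115)
  mass <- rtruncnorm(n, spec$mass_mean[[s]], spec$mass_sd[[s]], 40, 150)
  b <- .eb_new_coef[[s]]
  lp <- b["intercept"] + b["age"] * age + b["hr_per_po"] * hr_per_po +
    b["delta_po"] * delta_po + b["hr_standard"] * hr_standard
  noise <- if (spec$ln_noise_sd > 0) stats::rnorm(n, 0, spec$ln_noise_sd)
           else 0
  tibble::tibble(
    sex = s, age = age, body_mass = mass,
    po_standard = spec$po_standard,
    po_high = spec$po_standard + delta_po,
    hr_standard = hr_standard,
    hr_high = hr_standard + hr_per_po * delta_po,
    true_vo2max = exp(unname(lp)),
    measured_vo2max = exp(unname(lp) + noise)
  )
}

# oxygen cost of leg-ergometer cycling, L/min
vo2_of_power <- function(po_watts, mass_kg) {
  0.0108 * po_watts + 0.007 * mass_kg
}

generate_physiologic <- function(spec, s, n) {
  draw_one <- function() {
    for (attempt in seq_len(1000)) {
      age <- rtruncnorm(1, spec$age_mean[[s]], spec$age_sd[[s]],
                        spec$age_range[1], spec$age_range[2])
      mass <- rtruncnorm(1, spec$mass_mean[[s]], spec$mass_sd[[s]], 40, 150)
      vo2max <- rtruncnorm(1, spec$vo2max_mean[[s]], spec$vo2max_sd[[s]],
                           spec$vo2max_range[[s]][1],
                           spec$vo2max_range[[s]][2])
      hrmax <- spec$hrmax_intercept + spec$hrmax_slope * age +
        stats::rnorm(1, 0, spec$hrmax_sd)
      hr_rest <- rtruncnorm(1, spec$hr_rest_mean, spec$hr_rest_sd, 40, 90)
      vo2_rest <- 0.0035 * mass
      if (vo2max <= vo2_rest + 0.5 || hrmax <= hr_rest + 40) next
      slope <- (hrmax - hr_rest) / (vo2max - vo2_rest)  # bpm per L/min
      hr_at <- function(po) {
        hr_rest + slope * (vo2_of_power(po, mass) - vo2_rest)
      }
      hr_standard <- hr_at(spec$po_standard) +
        stats::rnorm(1, 0, spec$hr_noise_sd)
      target_vo2 <- vo2_rest +
        (spec$target_hrmax_frac * hrmax - hr_rest) / slope
      po_high <- 5 * round(((target_vo2 - 0.007 * mass) / 0.0108) / 5)
      po_high <- max(po_high, spec$po_standard + 25)
      hr_high <- hr_at(po_high) + stats::rnorm(1, 0, spec$hr_noise_sd)
      ok <- hr_high > hr_standard + 5 && hr_high < hrmax &&
        hr_standard > 40 && po_high > spec$po_standard
      if (ok) {
        return(tibble::tibble(
          sex = s, age = age, body_mass = mass,
          po_standard = spec$po_standard, po_high = po_high,
          hr_standard = hr_standard, hr_high = hr_high,
          true_vo2max = vo2max, measured_vo2max = vo2max))
      }
    }
    stop("spec error: rejection sampling failed after 1000 attempts; ",
         "the physiologic spec is infeasible", call. = FALSE)
  }
  dplyr::bind_rows(lapply(seq_len(n), function(i) draw_one()))
}

#' Simulate within-stage heart-rate readings for a record
#'
#' Emits the four protocol readings (3:15, 3:30, 3:45, 4:00 min) for one
#' stage as positive integers jittered by at most `jitter` bpm around the
#' stage's steady-state heart rate, constructed so that their mean is
#' within 1 bpm of the stored value. A fixture generator for
#' [steady_state_hr()].
#'
#' @param hr the stage's steady-state heart rate (bpm).
#' @param jitter maximum absolute integer jitter per reading (default 2).
#' @return a tibble with `time` ("m:ss"), `time_s` and integer `hr`.
#' @export
hr_series_for <- function(hr, jitter = 2) {
  stopifnot(length(hr) == 1, hr > 0, jitter >= 0)
  base <- as.integer(round(hr))
  off <- sample(seq(-jitter, jitter), 4, replace = TRUE)
  readings <- base + off
  # nudge readings toward hr until the mean is within 1 bpm
  while (abs(mean(readings) - hr) > 1) {
    dir <- sign(hr - mean(readings))
    movable <- which(abs(readings + dir - base) <= jitter)
    readings[movable[1]] <- readings[movable[1]] + dir
  }
  tibble::tibble(time = .protocol_labels, time_s = .protocol_offsets,
                 hr = as.integer(readings))
}
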