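#' Convert ergometer braking force and cadence to mechanical power
#'
#' On a friction-braked cycle ergometer the work rate is the braking force
#' (in kilopond, kp) times the flywheel travel per pedal revolution times the
#' cadence. The Monark convention is 6 m of flywheel travel per revolution,
#' and 1 W = 6.116 kpm/min, so the standard stage of 0.5 kp at 60 rpm is
#' 0.5 * 6 * 60 / 6.116 = 29.43 W (usually quoted as "about 30 W").
#'
#' @param resistance braking force in kilopond (kp); non-negative.
#' @param cadence pedal frequency in revolutions per minute; non-negative.
#' @param flywheel_m flywheel travel per pedal revolution in metres
#'   (default 6, the Monark convention).
#' @return power in watts, vectorised over the inputs.
#' @examples
#' kp_rpm_to_watts(0.5, 60) # 29.43 W, the standard stage
#' @export
kp_rpm_to_watts <- function(resistance, cadence, flywheel_m = 6) {
  if (any(resistance < 0, na.rm = TRUE) || any(cadence < 0, na.rm = TRUE)) {
    stop("invalid argument: resistance and cadence must be non-negative",
         call. = FALSE)
  }
  if (flywheel_m <= 0) {
    stop("invalid argument: flywheel_m must be positive", call. = FALSE)
  }
  resistance * flywheel_m * cadence / 6.116
}

# protocol sampling offsets within a stage, in seconds
.protocol_offsets <- c(195L, 210L, 225L, 240L)
.protocol_labels <- c("3:15", "3:30", "3:45", "4:00")

#' Steady-state heart rate of a test stage
#'
#' The steady-state heart rate of a 4-min stage is the arithmetic mean of
#' the readings observed at 3:15, 3:30, 3:45 and 4:00 min. All four protocol
#' time points must be present; extra readings at other offsets are ignored.
#'
#' @param time time offsets within the stage, either in seconds (numeric) or
#'   as "m:ss" strings.
#' @param hr heart-rate readings (bpm) matching `time`.
#' @return steady-state heart rate in bpm.
#' @examples
#' steady_state_hr(c("3:15", "3:30", "3:45", "4:00"), c(118, 120, 122, 124))
#' @export
steady_state_hr <- function(time, hr) {
  stopifnot(length(time) == length(hr))
  secs <- parse_stage_time(time)
  idx <- match(.protocol_offsets, secs)
  if (anyNA(idx)) {
    missing <- .protocol_labels[is.na(idx)]
    stop("incomplete series: missing protocol time point(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- hr[idx]
  if (anyNA(vals)) {
    stop("incomplete series: NA heart rate at protocol time point(s) ",
         paste(.protocol_labels[is.na(vals)], collapse = ", "), call. = FALSE)
  }
  mean(vals)
}

# "m:ss" -> seconds; numerics pass through
parse_stage_time <- function(time) {
  if (is.numeric(time)) return(as.integer(round(time)))
  parts <- strsplit(as.character(time), ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) == 1L) return(as.integer(round(as.numeric(p))))
    as.integer(p[1L]) * 60L + as.integer(p[2L])
  }, integer(1))
}
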