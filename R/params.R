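#' Behavioral parameters for the trajectory simulator
#'
#' Parameterizes a marmoset-like locomotor model: a two-state (rest/locomote)
#' Markov chain drives horizontal motion, with per-frame locomotion speeds
#' drawn from a gamma distribution (shape 4) whose mean is
#' `speed_scale_cm_s`; Poisson-scheduled jump/climb events superimpose a
#' brief vertical excursion; the animal is confined to a fraction of the cage
#' volume.
#'
#' Defaults describe a healthy adult animal: roughly 30% of time in motion,
#' a 20 cm/s mean locomotion speed, two jump/climb events per minute with a
#' 150 cm/s peak vertical speed, and use of the full cage.
#'
#' @param p_rest_to_move,p_move_to_rest Per-frame transition probabilities of
#'   the rest/locomote chain, in `[0, 1]`.
#' @param speed_scale_cm_s Mean horizontal speed while locomoting (cm/s).
#' @param jump_rate_per_min Poisson rate of jump/climb events (events/min).
#' @param jump_peak_speed_cm_s Peak vertical speed during an event (cm/s);
#'   settable above or below the 120 cm/s jump/climb detection threshold.
#' @param range_fraction Fraction `(0, 1]` of the cage volume the animal
#'   uses; each linear dimension is scaled by `range_fraction^(1/3)`, the
#'   vertical range anchored at the floor.
#' @param seed Optional RNG seed attached to the parameters.
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(p_rest_to_move = 0.02, p_move_to_rest = 0.05,
                            speed_scale_cm_s = 20, jump_rate_per_min = 2,
                            jump_peak_speed_cm_s = 150, range_fraction = 1,
                            seed = NULL) {
  p <- list(p_rest_to_move = p_rest_to_move, p_move_to_rest = p_move_to_rest,
            speed_scale_cm_s = speed_scale_cm_s,
            jump_rate_per_min = jump_rate_per_min,
            jump_peak_speed_cm_s = jump_peak_speed_cm_s,
            range_fraction = range_fraction, seed = seed)
  class(p) <- "behavior_params"
  validate_behavior_params(p)
  p
}

validate_behavior_params <- function(p) {
  chk <- function(field, lo, hi, lo_open = FALSE) {
    v <- p[[field]]
    bad <- !is.numeric(v) || length(v) != 1 || !is.finite(v) ||
      v < lo || v > hi || (lo_open && v <= lo)
    if (bad)
      stop("behavior_params: field '", field, "' out of range", call. = FALSE)
  }
  chk("p_rest_to_move", 0, 1)
  chk("p_move_to_rest", 0, 1)
  chk("speed_scale_cm_s", 0, Inf)
  chk("jump_rate_per_min", 0, Inf)
  chk("jump_peak_speed_cm_s", 0, Inf)
  chk("range_fraction", 0, 1, lo_open = TRUE)
  invisible(p)
}

#' @export
print.behavior_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<behavior_params> p(rest->move) %.3g, p(move->rest) %.3g, ",
    "speed %.3g cm/s,\n  jumps %.3g /min (peak vz %.3g cm/s), ",
    "range fraction %.3g\n"),
    x$p_rest_to_move, x$p_move_to_rest, x$speed_scale_cm_s,
    x$jump_rate_per_min, x$jump_peak_speed_cm_s, x$range_fraction))
  invisible(x)
}

#' Post-stroke deficit and exponential recovery schedule
#'
#' Describes how behavioral parameters change after a stroke: each affected
#' channel `c` is scaled by `1 - deficit[c] * exp(-(day - onset_day) / tau)`
#' for `day >= onset_day`, i.e. the deficit is maximal at `onset_day` and
#' decays exponentially back to baseline with time constant
#' `recovery_tau_days`. Days before `onset_day` return the baseline.
#'
#' Channels map onto parameters as: `speed` -> `speed_scale_cm_s`,
#' `activity` -> `p_rest_to_move`, `jump` -> `jump_rate_per_min`,
#' `range` -> `range_fraction`.
#'
#' @param baseline A [behavior_params()] describing the healthy state.
#' @param deficit Named numeric vector in `[0, 1]` over channels
#'   `speed`, `activity`, `jump`, `range` (missing channels mean 0).
#' @param recovery_tau_days Exponential recovery time constant (days, > 0).
#' @param onset_day Integer day at which the deficit is maximal.
#' @return An object of class `recovery_schedule`.
#' @export
recovery_schedule <- function(baseline = behavior_params(),
                              deficit = c(speed = 0.8, activity = 0.8,
                                          jump = 0.9, range = 0.8),
                              recovery_tau_days = 7, onset_day = 2L) {
  if (!inherits(baseline, "behavior_params"))
    stop("recovery_schedule: 'baseline' must be a behavior_params object",
         call. = FALSE)
  if (!is.numeric(recovery_tau_days) || length(recovery_tau_days) != 1 ||
      !is.finite(recovery_tau_days) || recovery_tau_days <= 0)
    stop("recovery_schedule: 'recovery_tau_days' must be > 0", call. = FALSE)
  known <- c("speed", "activity", "jump", "range")
  if (length(deficit) && (is.null(names(deficit)) ||
                          !all(names(deficit) %in% known)))
    stop("recovery_schedule: 'deficit' must be named with channels ",
         paste(known, collapse = ", "), call. = FALSE)
  if (any(!is.finite(deficit)) || any(deficit < 0) || any(deficit > 1))
    stop("recovery_schedule: 'deficit' values must lie in [0, 1]",
         call. = FALSE)
  d <- stats::setNames(numeric(4), known)
  d[names(deficit)] <- deficit
  s <- list(baseline = baseline, deficit = d,
            recovery_tau_days = recovery_tau_days,
            onset_day = as.integer(onset_day))
  class(s) <- "recovery_schedule"
  s
}

#' @export
print.recovery_schedule <- function(x, ...) {
  cat(sprintf(
    "<recovery_schedule> onset day %d, tau %g d, deficits: %s\n",
    x$onset_day, x$recovery_tau_days,
    paste(sprintf("%s %.2g", names(x$deficit), x$deficit), collapse = ", ")))
  invisible(x)
}

#' Behavioral parameters on a given study day
#'
#' Evaluates a [recovery_schedule()]: before `onset_day` the baseline is
#' returned unchanged; from `onset_day` on, each affected channel is scaled
#' by `1 - deficit * exp(-(day - onset_day) / tau)`. Deterministic, and
#' non-decreasing in `day` for every channel.
#'
#' @param schedule A [recovery_schedule()].
#' @param day Integer study day (negative = preoperative).
#' @return A [behavior_params()] for that day.
#' @export
apply_recovery <- function(schedule, day) {
  if (!inherits(schedule, "recovery_schedule"))
    stop("apply_recovery: 'schedule' must be a recovery_schedule",
         call. = FALSE)
  day <- as.integer(day)
  if (length(day) != 1 || is.na(day))
    stop("apply_recovery: 'day' must be a single integer", call. = FALSE)
  p <- schedule$baseline
  if (day < schedule$onset_day) return(p)
  decay <- exp(-(day - schedule$onset_day) / schedule$recovery_tau_days)
  scale <- 1 - schedule$deficit * decay
  p$speed_scale_cm_s <- p$speed_scale_cm_s * scale[["speed"]]
  p$p_rest_to_move <- p$p_rest_to_move * scale[["activity"]]
  p$jump_rate_per_min <- p$jump_rate_per_min * scale[["jump"]]
  p$range_fraction <- p$range_fraction * scale[["range"]]
  validate_behavior_params(p)
  p
}
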