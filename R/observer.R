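# Psychometric simulated observer.
#
# Per-response accuracy follows a logistic function of log stimulus duration
# between a guessing floor and a lapse-limited ceiling. The floor depends on
# the response kind: 0.5 for the central car/truck identification, 1/8 for
# the 8-location peripheral localisation. Training multiplies the duration
# threshold by `training_shift` (< 1 means faster processing after training).

#' Simulated-observer parameters
#'
#' Defaults are calibrated jointly against the two behaviours the paradigm
#' exhibits in healthy young adults: at the fixed 200 ms test duration,
#' per-response accuracy sits in the 82-94% band across task levels with
#' Task 4 clearly hardest; and during adaptive training the staircase climbs
#' through the levels (young adults' duration thresholds on the easy levels
#' are well below the 24 ms ladder floor, so >75% windows occur there and
#' level transitions fire), ending up hovering within Task 4 at mid-ladder
#' durations.
#'
#' @param threshold_ms Per-level duration (ms) at which the logistic sits at
#'   its midpoint, i.e. per-response accuracy is halfway between the guessing
#'   floor and the lapse-limited ceiling. Length 4, one value per task level.
#' @param slope Logistic steepness on the log-duration axis.
#' @param lapse_rate Probability of a stimulus-independent error; ceiling
#'   accuracy is `1 - lapse_rate`. Must be in [0, 0.5).
#' @param guess_floor Named guessing probabilities: `central` (2-alternative,
#'   0.5) and `peripheral` (8 locations, 0.125).
#' @param training_shift Multiplicative threshold reduction applied when
#'   simulating a trained observer; in (0, 1].
#' @param rt_mean_s,rt_sd_s Response-time model: truncated normal (>= 0.2 s).
#' @return List of class `observer_params`.
#' @export
observer_params <- function(threshold_ms = c(0.2, 0.7, 2, 10),
                            slope = 0.55,
                            lapse_rate = 0.05,
                            guess_floor = c(central = 0.5, peripheral = 0.125),
                            training_shift = 0.25,
                            rt_mean_s = 0.95,
                            rt_sd_s = 0.25) {
  if (length(threshold_ms) != 4L || any(threshold_ms <= 0)) {
    stop_invalid("`threshold_ms` must be 4 positive durations (one per level)")
  }
  slope <- check_positive(slope, "slope")
  if (!is.numeric(lapse_rate) || lapse_rate < 0 || lapse_rate >= 0.5) {
    stop_invalid("`lapse_rate` must lie in [0, 0.5)")
  }
  if (!all(c("central", "peripheral") %in% names(guess_floor))) {
    stop_invalid("`guess_floor` needs named elements `central` and `peripheral`")
  }
  if (any(guess_floor >= 1 - lapse_rate)) {
    stop_invalid("`guess_floor` must be below the ceiling 1 - lapse_rate")
  }
  if (training_shift <= 0 || training_shift > 1) {
    stop_invalid("`training_shift` must lie in (0, 1]")
  }
  structure(
    list(threshold_ms = threshold_ms, slope = slope, lapse_rate = lapse_rate,
         guess_floor = guess_floor, training_shift = training_shift,
         rt_mean_s = check_positive(rt_mean_s, "rt_mean_s"),
         rt_sd_s = check_positive(rt_sd_s, "rt_sd_s")),
    class = "observer_params"
  )
}

#' Per-response probability correct
#'
#' `p = floor + (1 - floor - lapse) * logistic(slope * (log d - log(threshold * shift)))`
#' where `shift = training_shift` for a trained observer and 1 otherwise.
#' The function is monotone non-decreasing in duration, tends to the guessing
#' floor as `d -> 0` and to `1 - lapse_rate` as `d -> Inf`, and equals the
#' midpoint of those two at the effective threshold.
#'
#' @param duration_ms Stimulus duration (ms), vectorised.
#' @param level Task level, 1-4.
#' @param response_kind `"central"` or `"peripheral"`.
#' @param observer [observer_params()].
#' @param trained Logical: apply the training threshold shift.
#' @return Probability (vector along `duration_ms`).
#' @export
p_correct <- function(duration_ms, level, response_kind = c("central", "peripheral"),
                      observer = observer_params(), trained = FALSE) {
  if (!is.numeric(duration_ms) || any(is.na(duration_ms)) || any(duration_ms <= 0)) {
    stop_invalid("`duration_ms` must be positive")
  }
  level <- check_level(level)
  response_kind <- match.arg(response_kind)
  trained <- check_flag(trained, "trained")
  if (response_kind == "peripheral" && level == 1L) {
    stop_invalid("level 1 has no peripheral response")
  }
  floor <- observer$guess_floor[[response_kind]]
  shift <- if (trained) observer$training_shift else 1
  theta <- observer$threshold_ms[level] * shift
  z <- observer$slope * (log(duration_ms) - log(theta))
  floor + (1 - floor - observer$lapse_rate) * stats::plogis(z)
}

# Internal response draw shared by the staircase loop and simulate_response;
# consumes the current RNG stream.
simulate_response_impl <- function(level, duration_ms, observer, trained, layout) {
  pc <- p_correct(duration_ms, level, "central", observer, trained)
  central <- as.integer(runif(1) < pc)
  peripheral <- NA_integer_
  if (level >= 2L) {
    pp <- p_correct(duration_ms, level, "peripheral", observer, trained)
    peripheral <- as.integer(runif(1) < pp)
  }
  rt <- rnorm(1, observer$rt_mean_s, observer$rt_sd_s)
  while (rt < 0.2) rt <- rnorm(1, observer$rt_mean_s, observer$rt_sd_s)
  list(central_correct = central, peripheral_correct = peripheral, rt_s = rt)
}

#' Simulate the responses of one trial
#'
#' Central and (for levels >= 2) peripheral responses are drawn independently
#' with their respective [p_correct()]; response time is a truncated normal
#' bounded below at 0.2 s.
#'
#' @param task_level Task level, 1-4.
#' @param stimulus_duration_ms Stimulus duration (ms).
#' @param observer [observer_params()].
#' @param trained Logical: apply the training threshold shift.
#' @return List with `central_correct`, `peripheral_correct` (`NA` for
#'   level 1), and `rt_s`.
#' @export
simulate_response <- function(task_level, stimulus_duration_ms,
                              observer = observer_params(), trained = FALSE) {
  level <- check_level(task_level)
  d <- check_positive(stimulus_duration_ms, "stimulus_duration_ms")
  simulate_response_impl(level, d, observer, trained, peripheral_layout())
}
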