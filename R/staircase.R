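# Adaptive processing-speed-training staircase.
#
# Training adjusts difficulty along two axes: a ladder of stimulus durations
# within a task level, and the task level itself once the ladder saturates.
# Every fourth trial a performance check counts the individual central and
# peripheral responses of the preceding four trials (8 possible responses at
# levels 2-4, 4 at level 1):
#   accuracy > 75%      -> harder (shorter duration, or next level at the
#                          shortest duration; Task 4 caps and keeps running
#                          at the shortest duration)
#   accuracy < 37.5%    -> easier (longer duration, or previous level at the
#                          longest duration; Task 1 is the floor)
#   otherwise           -> unchanged
# Both thresholds are strict, so exactly 75% (6 of 8) and exactly 37.5%
# (3 of 8) leave the difficulty unchanged.

#' Stimulus-duration ladder (ms), easiest (longest) first
#'
#' @return Numeric vector of permissible stimulus durations, strictly
#'   decreasing: 306, 259, 200, 153, 106, 82, 59, 35, 24.
#' @export
duration_ladder <- function() {
  c(306, 259, 200, 153, 106, 82, 59, 35, 24)
}

#' Number of scored responses per trial at a task level
#'
#' Task 1 has only the central identification; Tasks 2-4 add the peripheral
#' localisation, and the two responses are counted independently.
#' @param level Task level, 1-4.
#' @return 1 for level 1, 2 for levels 2-4.
#' @export
responses_per_trial <- function(level) {
  level <- check_level(level)
  if (level == 1L) 1L else 2L
}

#' Windowed accuracy as a percentage
#'
#' @param correct Number of correct responses in the window.
#' @param total Number of scored responses in the window (> 0).
#' @return `100 * correct / total`.
#' @examples
#' window_accuracy(6, 8)  # 75
#' @export
window_accuracy <- function(correct, total) {
  if (!is.numeric(total) || length(total) != 1L || is.na(total) || total <= 0) {
    stop_invalid("`total` must be a single positive count")
  }
  if (!is.numeric(correct) || length(correct) != 1L || is.na(correct) ||
      correct < 0 || correct > total) {
    stop_invalid("`correct` must lie in [0, total]")
  }
  100 * correct / total
}

#' Performance-check decision for a 4-trial window
#'
#' @inheritParams window_accuracy
#' @param up_threshold_pct,down_threshold_pct Strict thresholds (percent).
#' @return `"harder"`, `"easier"`, or `"same"`.
#' @examples
#' evaluate_window(7, 8)  # "harder"
#' evaluate_window(6, 8)  # "same": 75% is not greater than 75%
#' evaluate_window(2, 8)  # "easier"
#' @export
evaluate_window <- function(correct, total,
                            up_threshold_pct = 75, down_threshold_pct = 37.5) {
  acc <- window_accuracy(correct, total)
  if (acc > up_threshold_pct) "harder"
  else if (acc < down_threshold_pct) "easier"
  else "same"
}

#' Initial staircase state
#'
#' Training sessions start at Task 1 with a 200 ms stimulus duration.
#'
#' @param level Starting task level.
#' @param duration_ms Starting stimulus duration; must be on the ladder.
#' @param ladder Duration ladder, longest first.
#' @return A list of class `staircase_state`: `level`, `ladder_index`,
#'   `duration_ms`, plus the rolling window counters `trials_since_check`,
#'   `window_correct`, `window_total`.
#' @export
staircase_init <- function(level = 1L, duration_ms = 200,
                           ladder = duration_ladder()) {
  level <- check_level(level)
  idx <- match(duration_ms, ladder)
  if (is.na(idx)) {
    stop_invalid("`duration_ms` must be one of the ladder durations")
  }
  structure(
    list(level = level, ladder_index = idx, duration_ms = ladder[idx],
         trials_since_check = 0L, window_correct = 0L, window_total = 0L),
    class = "staircase_state"
  )
}

#' @export
print.staircase_state <- function(x, ...) {
  cat(sprintf("staircase: Task %d at %g ms (window %d/%d after %d trial(s))\n",
              x$level, x$duration_ms, x$window_correct, x$window_total,
              x$trials_since_check))
  invisible(x)
}

#' Apply a performance-check decision to the staircase state
#'
#' "Harder" steps one rung down the ladder; at the shortest duration it
#' advances the task level instead, keeping the duration (Task 4 saturates:
#' it keeps running at the shortest duration). "Easier" mirrors this upward,
#' saturating at Task 1 at the longest duration. Window counters reset after
#' every check so consecutive checks use disjoint 4-trial windows.
#'
#' @param state A `staircase_state`.
#' @param decision `"harder"`, `"easier"`, or `"same"`.
#' @param ladder Duration ladder, longest first.
#' @return The updated `staircase_state`.
#' @export
apply_decision <- function(state, decision, ladder = duration_ladder()) {
  stopifnot(inherits(state, "staircase_state"))
  decision <- match.arg(decision, c("harder", "easier", "same"))
  n_rungs <- length(ladder)

  if (decision == "harder") {
    if (state$ladder_index < n_rungs) {
      state$ladder_index <- state$ladder_index + 1L
    } else if (state$level < 4L) {
      state$level <- state$level + 1L
    } # Task 4 at the shortest duration: unchanged
  } else if (decision == "easier") {
    if (state$ladder_index > 1L) {
      state$ladder_index <- state$ladder_index - 1L
    } else if (state$level > 1L) {
      state$level <- state$level - 1L
    } # Task 1 at the longest duration: unchanged
  }
  state$duration_ms <- ladder[state$ladder_index]
  state$trials_since_check <- 0L
  state$window_correct <- 0L
  state$window_total <- 0L
  state
}

#' Run one adaptive training block against a simulated observer
#'
#' Trials are generated on the fly from the current staircase state (the
#' study's training blocks hold 375 trials each); after every fourth
#' completed trial a performance check is evaluated and applied. The trace
#' records each trial's pre-trial state, responses, and any check outcome.
#'
#' @param observer [observer_params()] describing the simulated participant.
#' @param n_trials Number of trials in the block (the study uses 375).
#' @param seed Integer seed; the trace is bit-reproducible given the seed.
#' @param trained Logical; if `TRUE` the observer's post-training threshold
#'   shift applies.
#' @param start State to begin from, default [staircase_init()].
#' @param check_every Trials between performance checks (default 4).
#' @param ladder Duration ladder.
#' @param layout Peripheral layout used to draw stimuli.
#' @return Data frame of class `staircase_trace` with one row per trial:
#'   `trial_index`, `task_level`, `stimulus_duration_ms`, `central_identity`,
#'   `peripheral_location`, `distractor_kind`, `central_correct`,
#'   `peripheral_correct` (`NA` at level 1), `rt_s`, `check_performed`,
#'   `decision` (`NA` between checks), `post_level`, `post_duration_ms`.
#' @examples
#' obs <- observer_params()
#' tr <- run_training_block(obs, n_trials = 40, seed = 1)
#' table(tr$task_level)
#' @export
run_training_block <- function(observer, n_trials, seed = 1L, trained = FALSE,
                               start = staircase_init(),
                               check_every = 4L,
                               ladder = duration_ladder(),
                               layout = peripheral_layout()) {
  n_trials <- check_count(n_trials, "n_trials")
  check_every <- check_count(check_every, "check_every")

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  state <- start
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    stim <- assign_stimuli(state$level, layout)
    spec <- list(task_level = state$level,
                 stimulus_duration_ms = state$duration_ms)
    resp <- simulate_response_impl(state$level, state$duration_ms, observer,
                                   trained, layout)

    correct_i <- resp$central_correct +
      (if (state$level >= 2L) resp$peripheral_correct else 0L)
    state$window_correct <- state$window_correct + correct_i
    state$window_total <- state$window_total + responses_per_trial(state$level)
    state$trials_since_check <- state$trials_since_check + 1L

    check <- state$trials_since_check == check_every
    decision <- NA_character_
    if (check) {
      decision <- evaluate_window(state$window_correct, state$window_total)
      state <- apply_decision(state, decision, ladder)
    }

    rows[[i]] <- data.frame(
      trial_index = i,
      task_level = spec$task_level,
      stimulus_duration_ms = spec$stimulus_duration_ms,
      central_identity = stim$central_identity,
      peripheral_location = stim$peripheral_location,
      distractor_kind = distractor_for_level(spec$task_level),
      central_correct = resp$central_correct,
      peripheral_correct = if (spec$task_level >= 2L) resp$peripheral_correct else NA_integer_,
      rt_s = resp$rt_s,
      check_performed = check,
      decision = decision,
      post_level = state$level,
      post_duration_ms = state$duration_ms,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  class(out) <- c("staircase_trace", "data.frame")
  out
}

#' @export
print.staircase_trace <- function(x, ...) {
  n_checks <- sum(x$check_performed)
  cat(sprintf("training trace: %d trials, %d performance checks\n",
              nrow(x), n_checks))
  last <- x[nrow(x), ]
  cat(sprintf("final state: Task %d at %g ms\n",
              last$post_level, last$post_duration_ms))
  invisible(as.data.frame(x))
}
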