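# Trial paradigm of the modified useful-field-of-view (UFOV) test: timing,
# task levels, peripheral geometry, and the fixed baseline/posttest schedule.
#
# The task has four levels of difficulty. Task 1 presents only a central
# stimulus (car or truck). Tasks 2-4 add a peripheral target in one of
# n_locations positions on a ring; Task 3 surrounds it with easily
# discriminable triangle distractors and Task 4 with target-like distractors.

#' Timing constants of the trial paradigm
#'
#' Every trial is a fixation cue (506 ms), the stimulus (variable duration),
#' a full-screen white-noise mask (1000 ms), and an unspeeded response probe.
#' @return Named numeric vector with elements `cue_ms` and `mask_ms`.
#' @export
paradigm_timing <- function() {
  c(cue_ms = 506, mask_ms = 1000)
}

#' Stimulus duration used during baseline and posttest phases (ms)
#' @export
test_duration_ms <- function() 200

distractor_for_level <- function(level) {
  c("none", "none", "triangle", "target_like")[level]
}

#' Peripheral stimulus layout
#'
#' Locations are spaced equally around a ring at a fixed eccentricity.
#' Location 0 sits at 12 o'clock and indices run clockwise (an arbitrary but
#' fixed convention; the study geometry is `n_locations = 8` at 5.7 degrees).
#'
#' @param n_locations Number of peripheral locations (>= 1).
#' @param eccentricity_deg Ring eccentricity in degrees of visual angle.
#' @param offset_rad Angle of location 0, measured clockwise from 12 o'clock.
#' @return A list of class `ufov_layout` with `n_locations`,
#'   `eccentricity_deg`, and `angles_rad` (clockwise from vertical).
#' @examples
#' peripheral_layout(8, 5.7)
#' @export
peripheral_layout <- function(n_locations = 8, eccentricity_deg = 5.7,
                              offset_rad = 0) {
  n_locations <- check_count(n_locations, "n_locations")
  eccentricity_deg <- check_positive(eccentricity_deg, "eccentricity_deg")
  structure(
    list(
      n_locations = n_locations,
      eccentricity_deg = eccentricity_deg,
      angles_rad = offset_rad + 2 * pi * (seq_len(n_locations) - 1L) / n_locations
    ),
    class = "ufov_layout"
  )
}

#' @export
print.ufov_layout <- function(x, ...) {
  cat(sprintf("UFOV peripheral layout: %d locations at %.1f deg eccentricity\n",
              x$n_locations, x$eccentricity_deg))
  invisible(x)
}

#' Segment timeline of a single trial
#'
#' @param stimulus_duration_ms Stimulus presentation duration in ms (> 0).
#' @return Data frame with columns `segment`, `onset_ms`, `offset_ms`
#'   (half-open intervals, contiguous); the probe row has `offset_ms = NA`
#'   because the response period is unspeeded.
#' @examples
#' trial_timeline(200)
#' @export
trial_timeline <- function(stimulus_duration_ms) {
  d <- check_positive(stimulus_duration_ms, "stimulus_duration_ms")
  tm <- paradigm_timing()
  onsets <- c(0, tm[["cue_ms"]], tm[["cue_ms"]] + d, tm[["cue_ms"]] + d + tm[["mask_ms"]])
  data.frame(
    segment = c("cue", "stimulus", "mask", "probe"),
    onset_ms = onsets,
    offset_ms = c(onsets[-1], NA_real_)
  )
}

probe_onset_ms <- function(timeline) {
  timeline$onset_ms[timeline$segment == "probe"]
}

#' Draw the stimulus content of one trial
#'
#' The central stimulus is a car on half of trials and a truck on the rest.
#' For levels >= 2 a peripheral target location is drawn uniformly over the
#' layout; Task 1 has no peripheral stimulus.
#'
#' @param level Task level, 1-4.
#' @param layout A [peripheral_layout()] object.
#' @return List with `central_identity` ("car"/"truck") and
#'   `peripheral_location` (0-based index, or `NA` for level 1).
#' @export
assign_stimuli <- function(level, layout = peripheral_layout()) {
  level <- check_level(level)
  central <- if (runif(1) < 0.5) "car" else "truck"
  loc <- if (level >= 2L) sample.int(layout$n_locations, 1L) - 1L else NA_integer_
  list(central_identity = central, peripheral_location = loc)
}

#' Build a baseline/posttest trial schedule
#'
#' Test phases run at a fixed 200 ms stimulus duration with the task level
#' incremented every `set_size` trials in the cycle 1, 2, 3, 4, 1, 2, ...;
#' one cycle of the four levels forms a set and the schedule holds `n_sets`
#' sets (the study uses 5 sets of 25-trial blocks, i.e. 500 trials). Central
#' identities are exactly balanced within each `set_size` block by a seeded
#' shuffle, which realises the 50/50 car/truck split deterministically;
#' peripheral locations are uniform over the layout for levels >= 2.
#'
#' @param n_sets Number of 4-level cycles (>= 1).
#' @param set_size Trials per task level within a cycle (>= 1).
#' @param seed Integer seed; the schedule is bit-reproducible given the seed.
#' @param layout A [peripheral_layout()] object.
#' @param phase Phase label stored on each trial ("baseline" or "posttest").
#' @param balance_identity If `TRUE` (default) car/truck is exactly balanced
#'   within each block; if `FALSE` it is Bernoulli(0.5) per trial.
#' @return Data frame of trials: `trial_index` (1-based), `phase`,
#'   `task_level`, `stimulus_duration_ms`, `central_identity`,
#'   `peripheral_location` (`NA` at level 1), `distractor_kind`.
#' @examples
#' sched <- build_test_schedule(5, 25, seed = 1)
#' nrow(sched)          # 500
#' table(sched$task_level)
#' @export
build_test_schedule <- function(n_sets, set_size, seed = 1L,
                                layout = peripheral_layout(),
                                phase = "baseline",
                                balance_identity = TRUE) {
  n_sets <- check_count(n_sets, "n_sets")
  set_size <- check_count(set_size, "set_size")
  phase <- match.arg(phase, c("baseline", "posttest", "training"))

  levels <- rep(rep(1:4, each = set_size), times = n_sets)
  n <- length(levels)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  if (balance_identity) {
    # exact 50/50 within each set_size block (odd block sizes alternate the
    # extra identity across blocks via the shuffle)
    central <- unlist(lapply(seq_len(n / set_size), function(b) {
      pool <- rep(c("car", "truck"), length.out = set_size)
      sample(pool)
    }))
  } else {
    central <- ifelse(runif(n) < 0.5, "car", "truck")
  }

  loc <- ifelse(levels >= 2L,
                sample.int(layout$n_locations, n, replace = TRUE) - 1L,
                NA_integer_)

  data.frame(
    trial_index = seq_len(n),
    phase = phase,
    task_level = levels,
    stimulus_duration_ms = rep(test_duration_ms(), n),
    central_identity = central,
    peripheral_location = as.integer(loc),
    distractor_kind = vapply(levels, distractor_for_level, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Append timeline event columns to a trial table
#'
#' @param trials A trial table as from [build_test_schedule()].
#' @return The same table with `cue_on_ms`, `stim_on_ms`, `mask_on_ms`,
#'   `probe_on_ms` columns added.
#' @export
add_trial_events <- function(trials) {
  tm <- paradigm_timing()
  d <- trials$stimulus_duration_ms
  trials$cue_on_ms <- 0
  trials$stim_on_ms <- tm[["cue_ms"]]
  trials$mask_on_ms <- tm[["cue_ms"]] + d
  trials$probe_on_ms <- tm[["cue_ms"]] + d + tm[["mask_ms"]]
  trials
}
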