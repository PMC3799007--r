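# Whole-study synthetic data generation.
#
# The default configuration reproduces the study conditions: 20 subjects
# randomized 10/10 to training or no-contact control; a 500-trial baseline
# test (5 sets of 25 trials per task level at 200 ms); for the trained group
# six training days of two 375-trial adaptive blocks; and a 500-trial
# posttest. Eye streams are sampled at 1000 Hz throughout.

#' Population model for task-evoked pupil amplitudes
#'
#' Group-level mean dilation amplitudes (percent of baseline, per task
#' level) plus between-subject and between-phase dispersion. Task 2 is the
#' normalization reference and is pinned at 0. Default pre-phase means put
#' Task 3 at the Task 2 level and Task 4 about +2.2% -- between the two
#' groups' baseline values of the study population -- and the post-training
#' means for the trained group are flattened to 0, emulating the trained
#' group's reduced load response; controls keep their baseline amplitudes.
#' During training, a trained subject's amplitudes interpolate linearly from
#' the pre to the post values across training days.
#'
#' @param pre Length-4 mean amplitudes (% of baseline) at baseline, both
#'   groups.
#' @param post_trained,post_control Length-4 mean amplitudes at posttest.
#' @param subject_sd Between-subject SD of a subject's amplitude offset
#'   (constant across phases), applied to the non-reference levels.
#' @param phase_sd Within-subject between-phase SD, applied per phase to the
#'   non-reference levels.
#' @return List of class `amplitude_model`.
#' @export
amplitude_model <- function(pre = c(-0.5, 0, 0, 2.2),
                            post_trained = c(-0.5, 0, 0, 0),
                            post_control = pre,
                            subject_sd = 2.0,
                            phase_sd = 1.5) {
  for (v in list(pre, post_trained, post_control)) {
    if (length(v) != 4L || any(!is.finite(v))) {
      stop_invalid("amplitude vectors must hold 4 finite values")
    }
  }
  structure(list(pre = pre, post_trained = post_trained,
                 post_control = post_control,
                 subject_sd = subject_sd, phase_sd = phase_sd),
            class = "amplitude_model")
}

# Draw one subject's realized amplitude vectors for both test phases.
# Level 2 stays exactly 0 (it defines the reference). Consumes the RNG.
draw_subject_amplitudes <- function(model, group) {
  free <- c(1L, 3L, 4L)
  subj_re <- numeric(4)
  subj_re[free] <- rnorm(3, 0, model$subject_sd)
  post_mean <- if (group == "trained") model$post_trained else model$post_control
  pre <- model$pre + subj_re
  post <- post_mean + subj_re
  pre[free] <- pre[free] + rnorm(3, 0, model$phase_sd)
  post[free] <- post[free] + rnorm(3, 0, model$phase_sd)
  pre[2] <- 0; post[2] <- 0
  list(pre = pre, post = post)
}

#' Study configuration
#'
#' Defaults mirror the study: 10 subjects per group, test phases of 5 sets
#' of 25 trials per level, six training days of two 375-trial blocks.
#' Smaller values scale the simulation down for quick runs.
#'
#' @param n_per_group Subjects per group.
#' @param n_sets,set_size Test-phase schedule structure (trials per phase =
#'   `n_sets * 4 * set_size`).
#' @param n_training_days,blocks_per_day,trials_per_block Training schedule
#'   (trained group only).
#' @param observer Population [observer_params()].
#' @param observer_subject_sd Lognormal SD of a subject's threshold
#'   multiplier (between-subject psychometric variability).
#' @param pupil [pupil_params()] (session baseline, noise, blinks, ...).
#' @param amplitudes [amplitude_model()].
#' @param record_training_eye Record eye streams during training (needed for
#'   the training trend; the dominant simulation cost).
#' @param reset_each_block Restart the staircase at Task 1 / 200 ms at every
#'   block (default) rather than carrying state across a day.
#' @param master_seed Integer; all randomness derives from it.
#' @return List of class `study_config`.
#' @export
study_config <- function(n_per_group = 10,
                         n_sets = 5, set_size = 25,
                         n_training_days = 6, blocks_per_day = 2,
                         trials_per_block = 375,
                         observer = observer_params(),
                         observer_subject_sd = 0.08,
                         pupil = pupil_params(),
                         amplitudes = amplitude_model(),
                         record_training_eye = TRUE,
                         reset_each_block = TRUE,
                         master_seed = 20131018) {
  cfg <- list(
    n_per_group = check_count(n_per_group, "n_per_group", min = 2L),
    n_sets = check_count(n_sets, "n_sets"),
    set_size = check_count(set_size, "set_size"),
    n_training_days = check_count(n_training_days, "n_training_days", min = 0L),
    blocks_per_day = check_count(blocks_per_day, "blocks_per_day"),
    trials_per_block = check_count(trials_per_block, "trials_per_block"),
    observer = observer, observer_subject_sd = observer_subject_sd,
    pupil = pupil, amplitudes = amplitudes,
    record_training_eye = isTRUE(record_training_eye),
    reset_each_block = isTRUE(reset_each_block),
    master_seed = check_count(master_seed, "master_seed", min = 0L)
  )
  class(cfg) <- "study_config"
  cfg
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(
    "study config: %d + %d subjects; test %d trials (%d sets x %d per level);\n",
    x$n_per_group, x$n_per_group, x$n_sets * 4 * x$set_size, x$n_sets, x$set_size))
  cat(sprintf("training %d day(s) x %d block(s) x %d trials; master seed %d\n",
              x$n_training_days, x$blocks_per_day, x$trials_per_block,
              x$master_seed))
  invisible(x)
}

#' Read a study configuration from JSON
#'
#' Scalar keys override [study_config()] defaults; nested `observer`,
#' `pupil`, and `amplitudes` objects override the corresponding parameter
#' constructors field by field. Unknown keys are an error.
#' @param path Path to a JSON document.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("n_per_group", "n_sets", "set_size", "n_training_days",
             "blocks_per_day", "trials_per_block", "observer_subject_sd",
             "record_training_eye", "reset_each_block", "master_seed",
             "observer", "pupil", "amplitudes")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop_invalid("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  build_sub <- function(ctor, spec) {
    if (is.null(spec)) return(ctor())
    do.call(ctor, as.list(spec))
  }
  args <- raw[setdiff(names(raw), c("observer", "pupil", "amplitudes"))]
  args$observer <- build_sub(observer_params, raw$observer)
  args$pupil <- build_sub(pupil_params, raw$pupil)
  args$amplitudes <- build_sub(amplitude_model, raw$amplitudes)
  do.call(study_config, args)
}

# One subject's fixed properties, derived deterministically from the master
# seed so subjects can be generated in any order.
subject_profile <- function(config, subject_index) {
  group <- if (subject_index <= config$n_per_group) "trained" else "control"
  sseed <- child_seed(config$master_seed, subject_index)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(sseed)
  obs <- config$observer
  obs$threshold_ms <- obs$threshold_ms * exp(rnorm(1, 0, config$observer_subject_sd))
  amps <- draw_subject_amplitudes(config$amplitudes, group)
  list(id = sprintf("S%02d", subject_index), index = subject_index,
       group = group, seed = sseed, observer = obs, amplitudes = amps)
}

# Simulate one test session (responses + eye stream) for a subject profile.
simulate_test_session <- function(config, profile, phase = c("baseline", "posttest"),
                                  seed_offset = 0L) {
  phase <- match.arg(phase)
  trained_now <- phase == "posttest" && profile$group == "trained"
  amp <- if (phase == "baseline") profile$amplitudes$pre else profile$amplitudes$post

  seed <- child_seed(profile$seed, 1000L + seed_offset)
  trials <- build_test_schedule(config$n_sets, config$set_size, seed = seed,
                                phase = if (phase == "baseline") "baseline" else "posttest")

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(child_seed(profile$seed, 2000L + seed_offset))

  n <- nrow(trials)
  cc <- integer(n); pc <- rep(NA_integer_, n); rt <- numeric(n)
  for (i in seq_len(n)) {
    r <- simulate_response_impl(trials$task_level[i],
                                trials$stimulus_duration_ms[i],
                                profile$observer, trained_now, NULL)
    cc[i] <- r$central_correct; pc[i] <- r$peripheral_correct; rt[i] <- r$rt_s
  }
  trials$central_correct <- cc
  trials$peripheral_correct <- pc
  trials$rt_s <- rt

  pupil <- config$pupil
  pupil$load_amplitude_pct <- amp
  gain <- session_gain(pupil)
  eye <- simulate_session_eye(trials, pupil, gain)
  list(phase = phase, trials = eye$events, samples = eye$samples, gain = gain)
}

# Simulate one training block (trace + optional eye stream).
simulate_training_block <- function(config, profile, day, block) {
  seed <- child_seed(profile$seed, 3000L + day * 10L + block)
  trace <- run_training_block(profile$observer, config$trials_per_block,
                              seed = seed, trained = FALSE)
  trace$phase <- "training"
  trace$trial_index <- seq_len(nrow(trace))

  samples <- NULL
  events <- NULL
  if (config$record_training_eye) {
    # amplitudes interpolate linearly from pre to post across training days
    frac <- if (config$n_training_days > 1) (day - 1) / (config$n_training_days - 1) else 0
    amp <- profile$amplitudes$pre +
      frac * (profile$amplitudes$post - profile$amplitudes$pre)
    amp[2] <- 0
    pupil <- config$pupil
    pupil$load_amplitude_pct <- amp

    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(child_seed(profile$seed, 4000L + day * 10L + block))
    gain <- session_gain(pupil)
    eye <- simulate_session_eye(trace, pupil, gain)
    samples <- eye$samples
    events <- eye$events
  }
  list(day = day, block = block, trace = trace,
       samples = samples, events = events)
}

#' Generate the full synthetic study on disk
#'
#' Writes, per subject: trial-event CSV, response columns, and eye-sample
#' TSV for the baseline and posttest sessions; and, for trained subjects,
#' per-block training traces (TSV) and eye streams. A `manifest.json` maps
#' subject -> group -> phase -> file paths and records every derived seed.
#' The whole study regenerates bit-identically from `master_seed`.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
generate_study <- function(config = study_config(), out_dir) {
  if (missing(out_dir)) stop_invalid("`out_dir` is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  n_total <- 2L * config$n_per_group
  manifest <- list(master_seed = config$master_seed, subjects = list())

  for (s in seq_len(n_total)) {
    profile <- subject_profile(config, s)
    sdir <- file.path(out_dir, profile$id)
    dir.create(sdir, showWarnings = FALSE)
    entry <- list(id = profile$id, group = profile$group, seed = profile$seed,
                  phases = list())

    for (phase in c("baseline", "posttest")) {
      ses <- simulate_test_session(config, profile, phase,
                                   seed_offset = if (phase == "baseline") 0L else 1L)
      ev_path <- file.path(sdir, paste0(phase, "_events.csv"))
      eye_path <- file.path(sdir, paste0(phase, "_eye.tsv"))
      ev <- ses$trials
      ev$peripheral_location <- ifelse(is.na(ev$peripheral_location), "",
                                       ev$peripheral_location)
      utils::write.csv(ev, ev_path, row.names = FALSE, quote = FALSE)
      write_eye_samples(ses$samples, eye_path,
                        metadata = sprintf("subject=%s phase=%s seed=%d",
                                           profile$id, phase, profile$seed))
      entry$phases[[phase]] <- list(events = ev_path, eye = eye_path)
    }

    if (profile$group == "trained" && config$n_training_days > 0) {
      tr <- list()
      for (day in seq_len(config$n_training_days)) {
        for (block in seq_len(config$blocks_per_day)) {
          blk <- simulate_training_block(config, profile, day, block)
          base <- sprintf("training_day%d_block%d", day, block)
          trace_path <- file.path(sdir, paste0(base, "_trace.tsv"))
          utils::write.table(as.data.frame(blk$trace), trace_path, sep = "\t",
                             quote = FALSE, row.names = FALSE)
          files <- list(trace = trace_path)
          if (!is.null(blk$samples)) {
            eye_path <- file.path(sdir, paste0(base, "_eye.tsv"))
            write_eye_samples(blk$samples, eye_path,
                              metadata = sprintf("subject=%s day=%d block=%d",
                                                 profile$id, day, block))
            ev_path <- file.path(sdir, paste0(base, "_events.csv"))
            utils::write.csv(blk$events, ev_path, row.names = FALSE, quote = FALSE)
            files$eye <- eye_path
            files$events <- ev_path
          }
          tr[[base]] <- files
        }
      }
      entry$phases$training <- tr
    }
    manifest$subjects[[profile$id]] <- entry
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Simulate session condition means directly (condition-mean marginal)
#'
#' Draws, for every subject and test phase, the per-task mean windowed pupil
#' diameter implied by the eye-trace generator -- session gain times baseline
#' times `(1 + amplitude/100)`, plus the measurement noise a condition mean
#' carries after trial averaging -- and pushes it through the percent-change
#' normalization. This is the generator's condition-level marginal: the
#' plateau construction makes the windowed mean equal this expression
#' exactly, so large simulation studies of the statistics (e.g. null
#' calibration of the ANOVA) can run without synthesising millions of 1 ms
#' samples. The shared Task 2 denominator noise, which shapes the
#' correlation structure of the normalized values, is preserved exactly.
#'
#' @param config A [study_config()]; `amplitudes`, `pupil`, `n_per_group`
#'   are used.
#' @param meas_se_au SD of the measurement noise on a condition mean (au).
#'   `NULL` derives it from the pupil noise level and the trial counts:
#'   `sample_noise_au / sqrt(0.9 * 500 * n_trials_per_level)`.
#' @param seed Integer seed.
#' @return Long data frame: `subject`, `group`, `time` (pre/post),
#'   `task_level`, `mean_pupil_au`, `pct_change_from_task2`.
#' @export
simulate_condition_means <- function(config = study_config(),
                                     meas_se_au = NULL, seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  n_trials_per_level <- config$n_sets * config$set_size
  if (is.null(meas_se_au)) {
    meas_se_au <- config$pupil$sample_noise_au /
      sqrt(0.9 * 500 * n_trials_per_level)
  }
  n_total <- 2L * config$n_per_group
  rows <- list()
  for (s in seq_len(n_total)) {
    group <- if (s <= config$n_per_group) "trained" else "control"
    amps <- draw_subject_amplitudes(config$amplitudes, group)
    for (phase in c("pre", "post")) {
      amp <- if (phase == "pre") amps$pre else amps$post
      gain <- session_gain(config$pupil)
      m <- gain * config$pupil$baseline_au * (1 + amp / 100) +
        rnorm(4, 0, meas_se_au)
      means <- data.frame(task_level = 1:4, n_trials_used = n_trials_per_level,
                          n_trials_missing = 0L, mean_pupil_au = m)
      sm <- pct_change_from_task2(means, levels = 2:4)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sprintf("S%02d", s), group = group, time = phase,
        task_level = sm$task_level, mean_pupil_au = sm$mean_pupil_au,
        pct_change_from_task2 = sm$pct_change_from_task2)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
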