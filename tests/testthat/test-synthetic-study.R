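small_config <- function(seed = 11, ...) {
  study_config(n_per_group = 2, n_sets = 1, set_size = 2,
               n_training_days = 1, blocks_per_day = 1, trials_per_block = 20,
               record_training_eye = FALSE, master_seed = seed, ...)
}

test_that("defaults mirror the study conditions", {
  cfg <- study_config()
  expect_equal(cfg$n_per_group, 10L)
  expect_equal(cfg$n_sets * 4 * cfg$set_size, 500L)
  expect_equal(cfg$n_training_days * cfg$blocks_per_day, 12L)
  expect_equal(cfg$trials_per_block, 375L)
})

test_that("generate_study writes a complete, reproducible file layout", {
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  cfg <- small_config()
  man <- generate_study(cfg, dir_a)
  expect_equal(length(man$subjects), 4)
  groups <- vapply(man$subjects, `[[`, "", "group")
  expect_equal(unname(table(groups)), c(2L, 2L), ignore_attr = TRUE)

  for (sub in man$subjects) {
    for (phase in c("baseline", "posttest")) {
      expect_true(file.exists(sub$phases[[phase]]$events))
      expect_true(file.exists(sub$phases[[phase]]$eye))
    }
    if (sub$group == "trained") {
      expect_equal(length(sub$phases$training), 1)   # 1 day x 1 block
      expect_true(file.exists(sub$phases$training[[1]]$trace))
    } else {
      expect_null(sub$phases$training)
    }
  }
  expect_true(file.exists(file.path(dir_a, "manifest.json")))

  # bit-identical regeneration from the master seed
  generate_study(cfg, dir_b)
  f <- man$subjects[[1]]$phases$baseline$eye
  expect_identical(readLines(f),
                   readLines(file.path(dir_b, basename(dirname(f)), basename(f))))

  # written artifacts round-trip through the readers
  ev <- read_trial_events(man$subjects[[1]]$phases$baseline$events)
  expect_equal(nrow(ev), 1 * 4 * 2)
  expect_true(all(is.na(ev$peripheral_location[ev$task_level == 1])))
  eye <- read_eye_samples(man$subjects[[1]]$phases$baseline$eye)
  expect_true(all(diff(eye$t_ms) > 0))
})

test_that("an analyzed generated session recovers its injected amplitudes", {
  amps <- amplitude_model(pre = c(0, 0, 1, 2.5), subject_sd = 0, phase_sd = 0)
  cfg <- study_config(n_per_group = 2, n_sets = 1, set_size = 3,
                      n_training_days = 0,
                      pupil = pupil_params(sample_noise_au = 0,
                                           blink_rate_hz = 0,
                                           saccade_rate_hz = 0),
                      amplitudes = amps, master_seed = 4)
  dir <- withr::local_tempdir()
  man <- generate_study(cfg, dir)
  sub <- man$subjects[[1]]
  samples <- read_eye_samples(sub$phases$baseline$eye)
  events <- read_trial_events(sub$phases$baseline$events)
  an <- analyze_session(samples, events)
  got <- an$summary$pct_change_from_task2[match(2:4, an$summary$task_level)]
  expect_equal(got, c(0, 1, 2.5), tolerance = 1e-9)
})

test_that("session gain jitter never reaches percent-change outputs", {
  cfg <- study_config(n_per_group = 2, n_sets = 1, set_size = 2,
                      n_training_days = 0,
                      pupil = pupil_params(sample_noise_au = 0,
                                           blink_rate_hz = 0,
                                           saccade_rate_hz = 0,
                                           gain_jitter_pct = 0),
                      amplitudes = amplitude_model(subject_sd = 0, phase_sd = 0),
                      master_seed = 13)
  cfg_jitter <- cfg
  cfg_jitter$pupil$gain_jitter_pct <- 40
  a <- simulate_condition_means(cfg, meas_se_au = 0, seed = 3)
  b <- simulate_condition_means(cfg_jitter, meas_se_au = 0, seed = 3)
  expect_false(isTRUE(all.equal(a$mean_pupil_au, b$mean_pupil_au)))
  expect_equal(a$pct_change_from_task2, b$pct_change_from_task2,
               tolerance = 1e-12)
})

test_that("condition-mean simulation is deterministic and well-shaped", {
  cfg <- small_config()
  a <- simulate_condition_means(cfg, seed = 2)
  b <- simulate_condition_means(cfg, seed = 2)
  expect_identical(a, b)
  expect_equal(nrow(a), 4 * 2 * 3)      # subjects x phases x tasks 2-4
  expect_true(all(a$pct_change_from_task2[a$task_level == 2] == 0))
})
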