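test_that("run_study produces the full report shape deterministically", {
  cfg <- study_config(n_per_group = 3, n_sets = 1, set_size = 3,
                      n_training_days = 0, master_seed = 17)
  rep1 <- run_study(cfg)
  expect_s3_class(rep1, "study_report")
  expect_equal(nrow(rep1$summary_table), 12)    # 2 groups x 2 times x 3 tasks
  expect_setequal(names(rep1$summary_table),
                  c("group", "time", "task_level", "pupil_pct_change",
                    "percent_correct", "rt_s"))
  expect_true(all(rep1$summary_table$pupil_pct_change[
    rep1$summary_table$task_level == 2] == 0))
  expect_equal(nrow(rep1$anova_pupil), 7)        # 3 mains + 3 two-way + 1 three-way
  expect_equal(nrow(rep1$anova_diff), 3)

  rep2 <- run_study(cfg)
  expect_identical(rep1$summary_table, rep2$summary_table)
  expect_identical(rep1$anova_pupil, rep2$anova_pupil)
})

test_that("run_study writes intermediates when asked", {
  dir <- withr::local_tempdir()
  cfg <- study_config(n_per_group = 2, n_sets = 1, set_size = 2,
                      n_training_days = 0, master_seed = 23)
  run_study(cfg, out_dir = dir)
  expect_true(file.exists(file.path(dir, "summary_table.tsv")))
  expect_true(file.exists(file.path(dir, "anova_pupil.tsv")))
  expect_true(file.exists(file.path(dir, "S01_baseline_summary.tsv")))
})

test_that("training trend recovers a shrinking amplitude gap", {
  # amplitudes interpolate pre -> post across days; trained post is flat,
  # so the injected Task4 - Task2 gap decreases linearly to 0
  cfg <- study_config(n_per_group = 2, n_sets = 1, set_size = 2,
                      n_training_days = 3, blocks_per_day = 1,
                      trials_per_block = 120,
                      observer = observer_params(threshold_ms = rep(2, 4),
                                                 slope = 1.2),
                      pupil = pupil_params(sample_noise_au = 0,
                                           blink_rate_hz = 0,
                                           saccade_rate_hz = 0),
                      amplitudes = amplitude_model(pre = c(0, 0, 0, 2.4),
                                                   post_trained = c(0, 0, 0, 0),
                                                   subject_sd = 0, phase_sd = 0),
                      master_seed = 29)
  rep <- run_study(cfg)
  tt <- rep$training_trend
  expect_equal(tt$day, 1:3)
  expect_true(all(tt$n_subjects > 0))
  expect_equal(tt$mean_diff_pct, c(2.4, 1.2, 0), tolerance = 1e-9)

  flat <- cfg
  flat$amplitudes <- amplitude_model(pre = c(0, 0, 0, 2.4),
                                     post_trained = c(0, 0, 0, 2.4),
                                     post_control = c(0, 0, 0, 2.4),
                                     subject_sd = 0, phase_sd = 0)
  rep_flat <- run_study(flat)
  expect_equal(rep_flat$training_trend$mean_diff_pct, rep(2.4, 3),
               tolerance = 1e-9)

  # QC columns surface sparse-task days instead of silently dropping them
  expect_true(all(rep$trend_subject_days$flag %in%
                    c("", "low_n", "missing_task")))
  expect_true(all(rep$trend_subject_days$n_task4_trials >= 0))
})

test_that("flattened post-training amplitudes surface as a Group x Time interaction", {
  # realistic effect sizes at the study sample size, via the condition-mean
  # marginal of the generator; majority of seeds detect the interaction
  hits <- 0
  n_seeds <- 20
  for (seed in seq_len(n_seeds)) {
    cm <- simulate_condition_means(study_config(), seed = seed)
    ds <- difference_score(cm)
    ds <- merge(ds, unique(cm[c("subject", "group")]), by = "subject")
    a <- mixed_rm_anova(ds, dv = "difference_pct",
                        within = "time", between = "group")
    p <- a$p[a$effect == "group x time"]
    if (p < 0.05) hits <- hits + 1
  }
  expect_gt(hits, n_seeds / 2)
})

test_that("study config JSON round-trips with validation", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n_per_group = 3, set_size = 4,
                            observer = list(slope = 1.5),
                            pupil = list(baseline_au = 800),
                            master_seed = 7),
                       path, auto_unbox = TRUE)
  cfg <- read_study_config(path)
  expect_equal(cfg$n_per_group, 3L)
  expect_equal(cfg$set_size, 4L)
  expect_equal(cfg$observer$slope, 1.5)
  expect_equal(cfg$pupil$baseline_au, 800)
  expect_equal(cfg$n_sets, 5L)    # untouched default

  jsonlite::write_json(list(bogus_key = 1), path, auto_unbox = TRUE)
  expect_error(read_study_config(path), "unknown config key")
})
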