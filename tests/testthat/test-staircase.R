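test_that("dual-response counting and windowed accuracy follow the rules", {
  expect_equal(responses_per_trial(1), 1L)
  expect_equal(responses_per_trial(2), 2L)
  expect_equal(responses_per_trial(4), 2L)
  expect_error(responses_per_trial(5), "level")

  expect_equal(window_accuracy(6, 8), 75)
  expect_equal(window_accuracy(3, 8), 37.5)
  expect_equal(window_accuracy(0, 4), 0)
  expect_error(window_accuracy(1, 0), "total")
  expect_error(window_accuracy(9, 8), "correct")
})

test_that("check decisions use strict thresholds", {
  expect_equal(evaluate_window(7, 8), "harder")   # 87.5%
  expect_equal(evaluate_window(6, 8), "same")     # exactly 75%
  expect_equal(evaluate_window(2, 8), "easier")   # 25%
  expect_equal(evaluate_window(3, 8), "same")     # exactly 37.5%
  # level-1 windows have 4 responses; 37.5% is unattainable there
  expect_equal(evaluate_window(1, 4), "easier")   # 25%
  expect_equal(evaluate_window(2, 4), "same")     # 50%
  expect_equal(evaluate_window(4, 4), "harder")   # 100%
})

test_that("decisions move one step with saturation at the extremes", {
  ladder <- duration_ladder()
  expect_true(all(diff(ladder) < 0))

  s <- staircase_init(level = 2, duration_ms = 200)
  h <- apply_decision(s, "harder")
  expect_equal(h$level, 2L); expect_equal(h$duration_ms, 153)

  s <- staircase_init(level = 3, duration_ms = 24)
  h <- apply_decision(s, "harder")
  expect_equal(h$level, 4L); expect_equal(h$duration_ms, 24)

  s <- staircase_init(level = 4, duration_ms = 24)
  h <- apply_decision(s, "harder")
  expect_equal(h$level, 4L); expect_equal(h$duration_ms, 24)

  s <- staircase_init(level = 1, duration_ms = 306)
  e <- apply_decision(s, "easier")
  expect_equal(e$level, 1L); expect_equal(e$duration_ms, 306)

  s <- staircase_init(level = 2, duration_ms = 306)
  e <- apply_decision(s, "easier")
  expect_equal(e$level, 1L); expect_equal(e$duration_ms, 306)

  s <- staircase_init()
  s$window_correct <- 5L; s$window_total <- 8L; s$trials_since_check <- 4L
  u <- apply_decision(s, "same")
  expect_equal(u$duration_ms, 200)
  expect_equal(u$window_correct, 0L)
  expect_equal(u$window_total, 0L)
  expect_equal(u$trials_since_check, 0L)

  expect_error(staircase_init(duration_ms = 123), "ladder")
})


test_that("a perfect observer's trace matches the hand-simulated oracle", {
  tr <- run_training_block(perfect_observer(), 60, seed = 1)
  oracle <- oracle_trace(60, all_correct = TRUE)
  expect_true(all(tr$central_correct == 1L))
  expect_equal(tr$task_level, oracle$level)
  expect_equal(tr$stimulus_duration_ms, oracle$duration)
  expect_equal(tr$post_level, oracle$post_level)
  expect_equal(tr$post_duration_ms, oracle$post_duration)
  # ladder descends 200 -> 24 then levels ascend to 4 and stay
  expect_equal(unique(tr$stimulus_duration_ms), c(200, 153, 106, 82, 59, 35, 24))
  expect_equal(tr$post_level[nrow(tr)], 4L)
  expect_equal(tr$post_duration_ms[nrow(tr)], 24)
})

test_that("an all-wrong observer saturates at Task 1, 306 ms", {
  tr <- run_training_block(awful_observer(), 40, seed = 2)
  oracle <- oracle_trace(40, all_correct = FALSE)
  expect_true(all(tr$central_correct == 0L))
  expect_equal(tr$stimulus_duration_ms, oracle$duration)
  expect_equal(unique(tr$stimulus_duration_ms), c(200, 259, 306))
  expect_true(all(tr$task_level == 1L))
})

test_that("a 375-trial block performs 93 checks and is reproducible", {
  tr <- run_training_block(observer_params(), 375, seed = 9)
  expect_equal(nrow(tr), 375)
  expect_equal(sum(tr$check_performed), 93)
  expect_identical(tr, run_training_block(observer_params(), 375, seed = 9))
})

test_that("state changes only at checks, one step at a time", {
  for (seed in 1:3) {
    tr <- run_training_block(observer_params(), 100, seed = seed)
    between <- !tr$check_performed
    expect_equal(tr$post_level[between], tr$task_level[between])
    expect_equal(tr$post_duration_ms[between], tr$stimulus_duration_ms[between])
    at <- tr[tr$check_performed, ]
    ladder <- duration_ladder()
    dl <- abs(at$post_level - at$task_level)
    di <- abs(match(at$post_duration_ms, ladder) -
                match(at$stimulus_duration_ms, ladder))
    expect_true(all(dl <= 1))
    expect_true(all(di <= 1))
    expect_true(all(dl * di == 0))   # never both in the same check
  }
})

test_that("the staircase concentrates where windowed accuracy is mid-range", {
  tr <- run_training_block(observer_params(), 1000, seed = 4)
  second_half <- tr[tr$trial_index > 500, ]
  occ <- table(paste(second_half$task_level, second_half$stimulus_duration_ms))
  modal <- names(occ)[which.max(occ)]
  parts <- as.numeric(strsplit(modal, " ")[[1]])
  obs <- observer_params()
  pc <- p_correct(parts[2], parts[1], "central", obs)
  pp <- if (parts[1] >= 2) p_correct(parts[2], parts[1], "peripheral", obs) else NULL
  acc <- 100 * mean(c(pc, pp))
  # expected accuracy at the modal state lies in (or near) the hold band
  expect_gt(acc, 30)
  expect_lt(acc, 80)
})

test_that("observers above 75% at 24 ms always reach Task 4 within a block", {
  for (seed in 1:5) {
    tr <- run_training_block(fast_observer(), 375, seed = seed)
    expect_equal(tr$post_level[375], 4L)
  }
})
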