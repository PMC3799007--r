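# End-to-end workflow: generate -> (train) -> measure -> normalize -> test.

behavior_summary <- function(trials, levels = 2:4) {
  out <- lapply(levels, function(l) {
    rows <- trials[trials$task_level == l, ]
    resp <- c(rows$central_correct,
              rows$peripheral_correct[!is.na(rows$peripheral_correct)])
    data.frame(task_level = l,
               accuracy_pct = 100 * mean(resp),
               rt_s = mean(rows$rt_s))
  })
  do.call(rbind, out)
}

analyze_subject_phase <- function(config, ses) {
  an <- analyze_session(ses$samples, ses$trials)
  beh <- behavior_summary(ses$trials)
  merge(an$summary, beh, by = "task_level")
}

#' Run the full synthetic study end to end
#'
#' Simulates every subject (baseline test, adaptive training for the
#' trained group, posttest), runs the pupil measurement pipeline on each
#' session's eye stream, normalizes to percent change from Task 2, and
#' computes the study's statistics: the summary table (group x time x task:
#' pupil percent change, accuracy, reaction time), three-factor
#' repeated-measures ANOVAs for pupil, accuracy, and reaction time, the
#' two-factor ANOVA on the Task 4 - Task 2 difference, post-hoc t tests,
#' and -- when training eye streams are recorded -- the per-day training
#' trend of the Task 4 - Task 2 pupil difference.
#'
#' The report is bit-reproducible from `config$master_seed` and invariant
#' to the order in which subjects are processed.
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given, per-subject intermediate
#'   tables (condition summaries, training traces) are written there.
#' @return A list of class `study_report`; see Details.
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_total <- 2L * config$n_per_group

  subject_rows <- list()
  trend_rows <- list()
  for (s in seq_len(n_total)) {
    profile <- subject_profile(config, s)
    for (phase in c("baseline", "posttest")) {
      ses <- simulate_test_session(config, profile, phase,
                                   seed_offset = if (phase == "baseline") 0L else 1L)
      sm <- analyze_subject_phase(config, ses)
      sm <- cbind(subject = profile$id, group = profile$group,
                  time = if (phase == "baseline") "pre" else "post", sm)
      subject_rows[[length(subject_rows) + 1L]] <- sm
      if (!is.null(out_dir)) {
        utils::write.table(sm, file.path(out_dir, sprintf("%s_%s_summary.tsv",
                                                          profile$id, phase)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    if (profile$group == "trained" && config$n_training_days > 0 &&
        config$record_training_eye) {
      for (day in seq_len(config$n_training_days)) {
        blk <- simulate_training_block(config, profile, day, 1L)
        trend_rows[[length(trend_rows) + 1L]] <-
          cbind(subject = profile$id, training_day_trend(blk, config))
        if (!is.null(out_dir)) {
          utils::write.table(as.data.frame(blk$trace),
                             file.path(out_dir, sprintf("%s_day%d_trace.tsv",
                                                        profile$id, day)),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
    }
  }
  subject_summaries <- do.call(rbind, subject_rows)
  rownames(subject_summaries) <- NULL

  report <- build_study_report(config, subject_summaries,
                               if (length(trend_rows)) do.call(rbind, trend_rows) else NULL)
  if (!is.null(out_dir)) {
    utils::write.table(report$summary_table,
                       file.path(out_dir, "summary_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(report$anova_pupil),
                       file.path(out_dir, "anova_pupil.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

# Per-day Task4 - Task2 pupil difference of one training block, through the
# same measurement pipeline as the test phases (unequal trial counts per
# task are inherent to adaptive training and are reported alongside).
training_day_trend <- function(blk, config) {
  an <- analyze_session(blk$samples, blk$events, normalize = FALSE)
  means <- session_condition_means(an$trial_measures)
  n2 <- sum(means$n_trials_used[means$task_level == 2L])
  n4 <- sum(means$n_trials_used[means$task_level == 4L])
  diff <- NA_real_
  flag <- ""
  ok2 <- n2 > 0
  ok4 <- n4 > 0
  if (ok2 && ok4) {
    sm <- pct_change_from_task2(means, levels = c(2L, 4L))
    diff <- sm$pct_change_from_task2[sm$task_level == 4L]
    if (min(n2, n4) < 4) flag <- "low_n"
  } else {
    flag <- "missing_task"
  }
  data.frame(day = blk$day, n_task2_trials = if (ok2) n2 else 0L,
             n_task4_trials = if (ok4) n4 else 0L,
             task4_minus_task2_pct = diff, flag = flag,
             stringsAsFactors = FALSE)
}

#' Per-day training trend of the Task 4 - Task 2 pupil difference
#'
#' Uses the first block of each training day of each trained subject,
#' normalized exactly as the test phases. Days where the staircase produced
#' no Task 2 (or Task 4) trials yield a missing value flagged
#' `missing_task`; days with fewer than 4 trials in either task are flagged
#' `low_n` (adaptive training concentrates trials at the hardest reached
#' level, so early tasks can be sparsely sampled).
#'
#' @param per_subject_days Data frame of per-subject per-day rows as
#'   produced inside [run_study()] (columns `subject`, `day`,
#'   `task4_minus_task2_pct`, trial counts, `flag`).
#' @return Data frame: per `day`, the across-subject mean difference, its
#'   SD, and the number of contributing subjects.
#' @export
training_trend <- function(per_subject_days) {
  days <- sort(unique(per_subject_days$day))
  out <- lapply(days, function(d) {
    v <- per_subject_days$task4_minus_task2_pct[per_subject_days$day == d]
    data.frame(day = d,
               n_subjects = sum(!is.na(v)),
               mean_diff_pct = if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_,
               sd_diff_pct = if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) else NA_real_)
  })
  do.call(rbind, out)
}

build_study_report <- function(config, subject_summaries, trend_subject_days) {
  d <- subject_summaries
  d$time <- factor(d$time, levels = c("pre", "post"))
  d$task <- factor(d$task_level)
  d$group <- factor(d$group, levels = c("trained", "control"))

  # Table-2-shaped summary: group x time x task cell means
  cells <- expand.grid(time = levels(d$time), group = levels(d$group),
                       task_level = 2:4, KEEP.OUT.ATTRS = FALSE)
  cells <- cells[order(cells$group, cells$time, cells$task_level), ]
  agg <- function(col) {
    mapply(function(tm, gr, tk) {
      mean(d[[col]][d$time == tm & d$group == gr & d$task_level == tk])
    }, cells$time, cells$group, cells$task_level)
  }
  summary_table <- data.frame(
    group = cells$group, time = cells$time, task_level = cells$task_level,
    pupil_pct_change = round(agg("pct_change_from_task2"), 2),
    percent_correct = round(agg("accuracy_pct")),
    rt_s = round(agg("rt_s"), 2))
  rownames(summary_table) <- NULL

  anova_pupil <- mixed_rm_anova(d, dv = "pct_change_from_task2",
                                within = c("time", "task"), between = "group")
  anova_accuracy <- mixed_rm_anova(d, dv = "accuracy_pct",
                                   within = c("time", "task"), between = "group")
  anova_rt <- mixed_rm_anova(d, dv = "rt_s",
                             within = c("time", "task"), between = "group")

  # two-factor ANOVA on the Task4 - Task2 difference (Group x Time)
  diffs <- difference_score(d)
  diffs$time <- factor(diffs$time, levels = c("pre", "post"))
  dg <- unique(d[c("subject", "group")])
  diffs <- merge(diffs, dg, by = "subject")
  anova_diff <- mixed_rm_anova(diffs, dv = "difference_pct",
                               within = "time", between = "group")

  # post-hoc t tests at baseline (both groups pooled) and the follow-up
  # two-sample t on the per-subject (post - pre) change of the difference
  pre <- d[d$time == "pre", ]
  wide <- function(task) pre$pct_change_from_task2[order(pre$subject)][
    pre$task_level[order(pre$subject)] == task]
  t_42 <- paired_t(wide(4), wide(2))
  t_43 <- paired_t(wide(4), wide(3))
  t_32 <- paired_t(wide(3), wide(2))
  posthoc <- data.frame(
    comparison = c("task4_vs_task2_pre", "task4_vs_task3_pre", "task3_vs_task2_pre"),
    t = c(t_42$t, t_43$t, t_32$t),
    df = c(t_42$df, t_43$df, t_32$df),
    p = c(t_42$p, t_43$p, t_32$p))

  dd <- merge(diffs[diffs$time == "pre", c("subject", "group", "difference_pct")],
              diffs[diffs$time == "post", c("subject", "difference_pct")],
              by = "subject", suffixes = c("_pre", "_post"))
  dd$change <- dd$difference_pct_post - dd$difference_pct_pre
  t_follow <- two_sample_t(dd$change[dd$group == "trained"],
                           dd$change[dd$group == "control"])
  followup <- data.frame(comparison = "trained_vs_control_change_in_diff",
                         t = t_follow$t, df = t_follow$df, p = t_follow$p)

  trend <- if (!is.null(trend_subject_days)) training_trend(trend_subject_days) else NULL

  structure(
    list(config = config,
         subject_summaries = subject_summaries,
         summary_table = summary_table,
         anova_pupil = anova_pupil,
         anova_accuracy = anova_accuracy,
         anova_rt = anova_rt,
         anova_diff = anova_diff,
         posthoc = posthoc,
         followup = followup,
         trend_subject_days = trend_subject_days,
         training_trend = trend),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("Synthetic processing-speed-training study report\n")
  cat(sprintf("subjects: %d trained + %d control\n\n",
              x$config$n_per_group, x$config$n_per_group))
  cat("Summary (pupil % change from Task 2, accuracy, RT):\n")
  print(x$summary_table, row.names = FALSE)
  cat("\nPupil percent-change ANOVA (Group x Time x Task):\n")
  print(x$anova_pupil)
  cat("\nTask4 - Task2 difference ANOVA (Group x Time):\n")
  print(x$anova_diff)
  if (!is.null(x$training_trend)) {
    cat("\nTraining trend (Task4 - Task2 pupil difference per day):\n")
    print(x$training_trend, row.names = FALSE)
  }
  invisible(x)
}
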