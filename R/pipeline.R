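# Pupil measurement pipeline.
#
# Mirrors the study's measurement logic: restrict to fixations (eye
# movements bias measured pupil size), restrict to the 500 ms window of
# interest immediately before the probe (the final 500 ms of the mask, where
# luminance is identical across conditions), average per trial, average per
# task level within a session, and express each level as percent change from
# the Task 2 mean -- which removes the session-specific arbitrary-unit gain.

#' Read an eye-sample TSV stream
#'
#' Expected columns: `t_ms`, `x`, `y`, `pupil_au`, `valid` (0/1). Leading
#' lines starting with `#` are metadata and are captured in the
#' `"metadata"` attribute. Timestamps must be strictly increasing; invalid
#' (blink) rows are retained and flagged -- filtering happens later.
#'
#' @param path Path to the TSV file.
#' @return Data frame of samples with attribute `metadata`.
#' @export
read_eye_samples <- function(path) {
  if (!file.exists(path)) stop_invalid("eye-sample file not found: ", path)
  lines_head <- readLines(path, n = 50L)
  meta <- grep("^#", lines_head, value = TRUE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, skip = length(meta),
                          data.table = FALSE)
  need <- c("t_ms", "x", "y", "pupil_au", "valid")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stop_invalid("malformed eye-sample file, missing column(s): ",
                 paste(missing_cols, collapse = ", "))
  }
  bad <- which(!is.finite(dt$t_ms) | !is.finite(dt$pupil_au) |
                 !(dt$valid %in% c(0, 1)))
  if (length(bad)) {
    stop_invalid(sprintf("malformed eye-sample row at data line %d of %s",
                         bad[1], path))
  }
  if (any(diff(dt$t_ms) <= 0)) {
    i <- which(diff(dt$t_ms) <= 0)[1]
    stop_invalid(sprintf(
      "non-monotone timestamps in %s (t_ms %g followed by %g)",
      path, dt$t_ms[i], dt$t_ms[i + 1]))
  }
  attr(dt, "metadata") <- meta
  dt
}

#' Write an eye-sample stream
#'
#' @param samples Sample data frame (`t_ms`, `x`, `y`, `pupil_au`, `valid`).
#' @param path Output path.
#' @param metadata Character vector written as `#`-prefixed header lines.
#' @export
write_eye_samples <- function(samples, path, metadata = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(metadata)) {
    writeLines(paste0("# ", sub("^#\\s*", "", metadata)), con)
  }
  utils::write.table(
    samples[, c("t_ms", "x", "y", "pupil_au", "valid")],
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trial-event CSV
#'
#' Counterpart of the event tables written by [generate_study()]; an empty
#' `peripheral_location` field (Task 1) is read as `NA`.
#' @param path Path to the CSV file.
#' @return Data frame of trials.
#' @export
read_trial_events <- function(path) {
  if (!file.exists(path)) stop_invalid("trial-event file not found: ", path)
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("peripheral_location" %in% names(ev)) {
    ev$peripheral_location <- suppressWarnings(as.integer(ev$peripheral_location))
  }
  ev
}

#' Detect fixations with a dispersion threshold (I-DT)
#'
#' Maximal runs of consecutive valid samples whose spatial dispersion
#' `(max x - min x) + (max y - min y)` stays within `dispersion_threshold`
#' and whose duration reaches `min_duration_ms` are emitted as fixations.
#' Invalid (blink) samples always terminate a run, so no fixation ever
#' contains an invalid sample. Intervals are half-open `[start_ms, end_ms)`.
#'
#' @param samples Time-ordered sample data frame (1 ms spacing).
#' @param dispersion_threshold Maximum summed x/y range within a fixation,
#'   in gaze units (degrees as abstract geometry). Default 1.0.
#' @param min_duration_ms Minimum fixation duration (ms). Default 100.
#' @return Data frame of fixations: `start_ms`, `end_ms`, `mean_x`,
#'   `mean_y`, `n_samples`.
#' @export
detect_fixations <- function(samples, dispersion_threshold = 1.0,
                             min_duration_ms = 100) {
  n <- nrow(samples)
  empty <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      mean_x = numeric(0), mean_y = numeric(0),
                      n_samples = integer(0))
  if (n == 0L) return(empty)

  valid <- samples$valid == 1
  t_ms <- samples$t_ms
  x <- samples$x
  y <- samples$y
  min_len <- as.integer(min_duration_ms)   # samples at 1 kHz

  # maximal valid runs (blink samples split)
  r <- rle(valid)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L

  out <- list()
  for (k in which(r$values)) {
    lo <- run_start[k]; hi <- run_end[k]
    i <- lo
    while (i + min_len - 1L <= hi) {
      j <- i + min_len - 1L
      xmin <- min(x[i:j]); xmax <- max(x[i:j])
      ymin <- min(y[i:j]); ymax <- max(y[i:j])
      if ((xmax - xmin) + (ymax - ymin) > dispersion_threshold) {
        i <- i + 1L
        next
      }
      while (j < hi) {
        nxmin <- min(xmin, x[j + 1L]); nxmax <- max(xmax, x[j + 1L])
        nymin <- min(ymin, y[j + 1L]); nymax <- max(ymax, y[j + 1L])
        if ((nxmax - nxmin) + (nymax - nymin) > dispersion_threshold) break
        j <- j + 1L
        xmin <- nxmin; xmax <- nxmax; ymin <- nymin; ymax <- nymax
      }
      out[[length(out) + 1L]] <- data.frame(
        start_ms = t_ms[i], end_ms = t_ms[j] + 1,
        mean_x = mean(x[i:j]), mean_y = mean(y[i:j]),
        n_samples = j - i + 1L)
      i <- j + 1L
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Window of interest of a trial
#'
#' The 500 ms immediately preceding probe onset, which coincides with the
#' final 500 ms of the white-noise mask; luminance is identical across
#' conditions there. Half-open interval.
#'
#' @param timeline A [trial_timeline()] data frame, or a single probe onset
#'   time in ms.
#' @param window_ms Window length (default 500 ms).
#' @return Numeric `c(start_ms, end_ms)`.
#' @examples
#' window_of_interest(trial_timeline(200))  # c(1206, 1706)
#' @export
window_of_interest <- function(timeline, window_ms = 500) {
  probe_on <- if (is.data.frame(timeline)) probe_onset_ms(timeline) else timeline
  c(start_ms = probe_on - window_ms, end_ms = probe_on)
}

#' Windowed pupil mean of one trial
#'
#' Mean pupil diameter over samples that lie inside the window of interest
#' and inside any detected fixation (sample-level intersection: a fixation
#' straddling the window edge contributes only its in-window samples).
#' With `method = "fixation"` the per-fixation means of the in-window
#' samples are averaged instead, weighting each contributing fixation
#' equally.
#'
#' @param samples Trial sample data frame.
#' @param fixations Fixations from [detect_fixations()].
#' @param window `c(start_ms, end_ms)` from [window_of_interest()].
#' @param method `"sample"` (default, sample-weighted) or `"fixation"`.
#' @return List: `mean_pupil_au` (`NA` if no usable sample),
#'   `n_window_samples`.
#' @export
trial_pupil <- function(samples, fixations, window, method = c("sample", "fixation")) {
  method <- match.arg(method)
  if (nrow(fixations) == 0L) {
    return(list(mean_pupil_au = NA_real_, n_window_samples = 0L))
  }
  t_ms <- samples$t_ms
  in_window <- t_ms >= window[[1]] & t_ms < window[[2]]
  per_fix <- numeric(0)
  sel <- rep(FALSE, nrow(samples))
  for (f in seq_len(nrow(fixations))) {
    in_fix <- in_window & t_ms >= fixations$start_ms[f] & t_ms < fixations$end_ms[f]
    if (any(in_fix)) {
      per_fix <- c(per_fix, mean(samples$pupil_au[in_fix]))
      sel <- sel | in_fix
    }
  }
  n_used <- sum(sel)
  if (n_used == 0L) {
    return(list(mean_pupil_au = NA_real_, n_window_samples = 0L))
  }
  m <- if (method == "sample") mean(samples$pupil_au[sel]) else mean(per_fix)
  list(mean_pupil_au = m, n_window_samples = as.integer(n_used))
}

#' Per-task mean pupil diameter of a session
#'
#' Unweighted mean over the non-missing per-trial windowed means of each
#' task level: the trial is the experimental unit, so unequal fixation
#' coverage does not reweight trials.
#'
#' @param measures Data frame of per-trial measures with `task_level` and
#'   `mean_pupil_au` (may contain `NA`).
#' @return Data frame: `task_level`, `n_trials_used`, `n_trials_missing`,
#'   `mean_pupil_au`.
#' @export
session_condition_means <- function(measures) {
  lv <- sort(unique(measures$task_level))
  out <- do.call(rbind, lapply(lv, function(l) {
    v <- measures$mean_pupil_au[measures$task_level == l]
    data.frame(task_level = l,
               n_trials_used = sum(!is.na(v)),
               n_trials_missing = sum(is.na(v)),
               mean_pupil_au = if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_)
  }))
  out
}

#' Percent change in pupil diameter from the Task 2 reference
#'
#' Task 2 is the reference (the only task with central and peripheral
#' stimuli and no distractors): its mean is defined to be zero and every
#' other level is expressed as `100 * (mean_t - mean_2) / mean_2`. Ratios of
#' within-session means cancel the arbitrary-unit gain, making values
#' comparable across sessions and participants.
#'
#' @param means Output of [session_condition_means()].
#' @param levels Task levels to report (default 2:4; Task 1 engages focused
#'   rather than divided attention and is excluded from analyses).
#' @return `means` restricted to `levels`, with a `pct_change_from_task2`
#'   column; the Task 2 row is exactly 0.
#' @export
pct_change_from_task2 <- function(means, levels = 2:4) {
  ref_row <- means[means$task_level == 2L, ]
  if (nrow(ref_row) != 1L || is.na(ref_row$mean_pupil_au)) {
    stop_invalid("Task 2 mean is missing: percent-change normalization undefined")
  }
  ref <- ref_row$mean_pupil_au
  if (ref <= 0) {
    stop_invalid("Task 2 mean must be positive for percent-change normalization")
  }
  out <- means[means$task_level %in% levels, , drop = FALSE]
  out$pct_change_from_task2 <- 100 * (out$mean_pupil_au - ref) / ref
  out$pct_change_from_task2[out$task_level == 2L] <- 0
  rownames(out) <- NULL
  out
}

#' Analyse one session's eye stream end to end
#'
#' Slices the session stream into trials (cue to probe), detects fixations
#' per trial, measures the windowed pupil mean, aggregates per task level,
#' and normalizes to percent change from Task 2.
#'
#' @param samples Session sample data frame (session-clock `t_ms`).
#' @param events Trial table with global `cue_on_ms` and `probe_on_ms`.
#' @param dispersion_threshold,min_duration_ms I-DT settings.
#' @param window_ms Window-of-interest length.
#' @param method Trial averaging method, see [trial_pupil()].
#' @param levels Task levels entering the summary (default 2:4).
#' @param normalize If `FALSE`, skip the percent-change summary (used for
#'   adaptive training blocks, where a task level may have no trials) and
#'   return `summary = NULL`.
#' @return List with `trial_measures` (per-trial QC table) and `summary`
#'   (per-task means with `pct_change_from_task2`).
#' @export
analyze_session <- function(samples, events,
                            dispersion_threshold = 1.0, min_duration_ms = 100,
                            window_ms = 500, method = "sample",
                            levels = 2:4, normalize = TRUE) {
  n <- nrow(events)
  t_all <- samples$t_ms
  meas <- vector("list", n)
  for (i in seq_len(n)) {
    lo <- events$cue_on_ms[i]; hi <- events$probe_on_ms[i]
    tr <- samples[t_all >= lo & t_all < hi, , drop = FALSE]
    fix <- detect_fixations(tr, dispersion_threshold, min_duration_ms)
    w <- window_of_interest(hi, window_ms)
    m <- trial_pupil(tr, fix, w, method)
    meas[[i]] <- data.frame(
      trial_index = events$trial_index[i],
      task_level = events$task_level[i],
      window_start_ms = w[[1]], window_end_ms = w[[2]],
      mean_pupil_au = m$mean_pupil_au,
      n_window_samples = m$n_window_samples,
      reason = if (m$n_window_samples == 0L) "no_fixation_in_window" else "")
  }
  trial_measures <- do.call(rbind, meas)
  summary <- NULL
  if (normalize) {
    means <- session_condition_means(trial_measures)
    summary <- pct_change_from_task2(means, levels)
  }
  list(trial_measures = trial_measures, summary = summary)
}
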