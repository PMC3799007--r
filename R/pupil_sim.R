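# Synthetic 1000 Hz eye-tracker streams.
#
# Pupil diameter is in arbitrary units (au), as eye trackers report it: the
# absolute scale depends on camera geometry and differs between sessions,
# which is what motivates the percent-change normalization downstream. Each
# simulated trial carries a load-dependent task-evoked dilation that rises
# after stimulus onset and plateaus well before the pre-probe window of
# interest, so the injected effect is exact inside the window. Luminance is
# constant by construction (the mask fills the screen), so no light reflex
# is modelled. Gaze is fixation-plus-jitter, broken by Poisson-rate saccades
# and blinks; blink samples are flagged invalid with pupil 0, as trackers
# report them.

#' Pupil/gaze generator parameters
#'
#' @param baseline_au Session-specific baseline pupil diameter in arbitrary
#'   units. The default 1000 au with `sample_noise_au = 2` mirrors the
#'   relative resolution of a research tracker (about 0.01 mm on a 5 mm
#'   pupil, i.e. 0.2%); an order-of-magnitude emulation, not a calibration.
#' @param load_amplitude_pct Length-4 vector: peak task-evoked dilation per
#'   task level, as percent of baseline. Task 2 is the reference condition
#'   and its amplitude should normally be 0; other levels are then read
#'   directly as percent change from Task 2.
#' @param response_latency_ms Delay from stimulus onset to the start of the
#'   evoked rise.
#' @param response_width_ms Duration of the smooth rise to plateau. With the
#'   defaults the plateau is reached 1006 ms into the trial, before the
#'   window of interest opens even at the shortest (24 ms) ladder duration.
#' @param sample_noise_au SD of additive white measurement noise (au).
#' @param blink_rate_hz,blink_duration_ms Poisson blink process; blink
#'   samples are invalid with pupil 0.
#' @param saccade_rate_hz,saccade_duration_ms Poisson saccade process; the
#'   gaze relocates smoothly to a new fixation position during a saccade.
#' @param saccade_amplitude Typical saccade size in gaze units (degrees of
#'   visual angle as abstract geometry).
#' @param fixation_jitter Gaze SD around a fixation position (same units).
#' @param gain_jitter_pct Session-to-session multiplicative gain spread
#'   (percent); see [session_gain()].
#' @return List of class `pupil_params`.
#' @export
pupil_params <- function(baseline_au = 1000,
                         load_amplitude_pct = c(-0.5, 0, 0, 2.2),
                         response_latency_ms = 100,
                         response_width_ms = 400,
                         sample_noise_au = 2,
                         blink_rate_hz = 0.1,
                         blink_duration_ms = 100,
                         saccade_rate_hz = 0.5,
                         saccade_duration_ms = 30,
                         saccade_amplitude = 3,
                         fixation_jitter = 0.05,
                         gain_jitter_pct = 5) {
  baseline_au <- check_positive(baseline_au, "baseline_au")
  if (length(load_amplitude_pct) != 4L || any(!is.finite(load_amplitude_pct))) {
    stop_invalid("`load_amplitude_pct` must be 4 finite values (one per level)")
  }
  structure(
    list(baseline_au = baseline_au,
         load_amplitude_pct = load_amplitude_pct,
         response_latency_ms = check_positive(response_latency_ms, "response_latency_ms"),
         response_width_ms = check_positive(response_width_ms, "response_width_ms"),
         sample_noise_au = sample_noise_au,
         blink_rate_hz = blink_rate_hz,
         blink_duration_ms = blink_duration_ms,
         saccade_rate_hz = saccade_rate_hz,
         saccade_duration_ms = saccade_duration_ms,
         saccade_amplitude = saccade_amplitude,
         fixation_jitter = fixation_jitter,
         gain_jitter_pct = gain_jitter_pct),
    class = "pupil_params"
  )
}

#' Evoked-dilation kernel
#'
#' Smooth raised-cosine rise from 0 to an exact plateau of 1, starting
#' `response_latency_ms` after stimulus onset and lasting
#' `response_width_ms`. The analysis only ever reads the plateau (the window
#' of interest), so the rise shape is immaterial to the measured effects.
#'
#' @param t_ms Trial times (ms from cue onset), vectorised.
#' @param stim_on_ms Stimulus onset (ms).
#' @param latency_ms,width_ms Kernel latency and rise duration.
#' @return Kernel values in [0, 1].
#' @export
evoked_kernel <- function(t_ms, stim_on_ms, latency_ms = 100, width_ms = 400) {
  s <- (t_ms - stim_on_ms - latency_ms) / width_ms
  s <- pmin(pmax(s, 0), 1)
  0.5 * (1 - cos(pi * s))
}

#' Draw a session gain factor
#'
#' Sessions differ multiplicatively in arbitrary-unit scale (camera/eye
#' geometry); the gain is lognormal with the configured percent spread.
#' Percent-change outputs are invariant to it by construction.
#' @param params [pupil_params()].
#' @return A single positive gain factor.
#' @export
session_gain <- function(params = pupil_params()) {
  exp(rnorm(1, 0, params$gain_jitter_pct / 100))
}

# Poisson event onsets over [0, n_ms); returns integer onset times.
poisson_onsets <- function(n_ms, rate_hz) {
  if (rate_hz <= 0) return(integer(0))
  gaps <- rexp(ceiling(n_ms / 1000 * rate_hz * 3) + 8, rate_hz) * 1000
  onsets <- cumsum(gaps)
  as.integer(floor(onsets[onsets < n_ms]))
}

#' Simulate the eye-sample stream of one trial
#'
#' One sample per millisecond from cue onset to probe onset. The pupil trace
#' is `gain * baseline * (1 + amplitude/100 * k(t)) + noise` with the
#' raised-cosine kernel `k`; gaze holds fixation at the screen centre with
#' Gaussian jitter, relocating during Poisson-rate saccades and dropping out
#' (invalid, pupil 0) during blinks.
#'
#' @param task_level Task level 1-4 (selects the evoked amplitude).
#' @param stimulus_duration_ms Stimulus duration (ms).
#' @param params [pupil_params()].
#' @param gain Session gain factor (default 1).
#' @param t_offset_ms Added to the emitted timestamps (session clock).
#' @return Data frame with `t_ms`, `x`, `y`, `pupil_au`, `valid` (0/1).
#'   Ground-truth saccade and blink onset times (trial-relative) are attached
#'   as attributes `saccade_onsets_ms` and `blink_onsets_ms` for validation.
#' @examples
#' eye <- simulate_trial_eye(4, 200, pupil_params(sample_noise_au = 0,
#'                                                blink_rate_hz = 0,
#'                                                saccade_rate_hz = 0))
#' range(eye$pupil_au)
#' @export
simulate_trial_eye <- function(task_level, stimulus_duration_ms,
                               params = pupil_params(), gain = 1,
                               t_offset_ms = 0) {
  level <- check_level(task_level)
  d <- check_positive(stimulus_duration_ms, "stimulus_duration_ms")
  tm <- paradigm_timing()
  stim_on <- tm[["cue_ms"]]
  probe_on <- tm[["cue_ms"]] + d + tm[["mask_ms"]]
  n <- as.integer(probe_on)              # samples at t = 0 .. probe_on - 1
  t_rel <- seq_len(n) - 1L

  amp <- params$load_amplitude_pct[level]
  k <- evoked_kernel(t_rel, stim_on, params$response_latency_ms,
                     params$response_width_ms)
  pupil <- gain * params$baseline_au * (1 + amp / 100 * k)
  if (params$sample_noise_au > 0) {
    pupil <- pupil + rnorm(n, 0, params$sample_noise_au)
  }

  # gaze: piecewise-constant fixation positions joined by short saccades
  x <- rnorm(n, 0, params$fixation_jitter)
  y <- rnorm(n, 0, params$fixation_jitter)
  sacc_on <- poisson_onsets(n, params$saccade_rate_hz)
  cx <- 0; cy <- 0
  for (s0 in sacc_on) {
    ang <- runif(1, 0, 2 * pi)
    r <- params$saccade_amplitude * (0.5 + runif(1))
    nx <- cx + r * cos(ang); ny <- cy + r * sin(ang)
    dur <- as.integer(params$saccade_duration_ms)
    idx_mv <- s0 + seq_len(min(dur, n - s0)) - 1L      # 0-based times
    frac <- seq_along(idx_mv) / length(idx_mv)
    x[idx_mv + 1L] <- x[idx_mv + 1L] + cx + frac * (nx - cx)
    y[idx_mv + 1L] <- y[idx_mv + 1L] + cy + frac * (ny - cy)
    first_after <- s0 + length(idx_mv)
    if (first_after <= n - 1L) {
      after <- first_after:(n - 1L)
      x[after + 1L] <- x[after + 1L] + nx
      y[after + 1L] <- y[after + 1L] + ny
    }
    cx <- nx; cy <- ny
  }

  valid <- rep(1L, n)
  blink_on <- poisson_onsets(n, params$blink_rate_hz)
  for (b0 in blink_on) {
    idx <- b0 + seq_len(min(as.integer(params$blink_duration_ms), n - b0)) - 1L
    valid[idx + 1L] <- 0L
  }
  pupil[valid == 0L] <- 0

  out <- data.frame(t_ms = t_rel + as.numeric(t_offset_ms),
                    x = x, y = y, pupil_au = pupil, valid = valid)
  attr(out, "saccade_onsets_ms") <- sacc_on
  attr(out, "blink_onsets_ms") <- blink_on
  out
}

#' Simulate the full eye stream of a session
#'
#' Concatenates per-trial streams on a running session clock: each trial's
#' samples cover its cue-to-probe interval; the (unsampled) response period
#' advances the clock by the trial's response time.
#'
#' @param trials Trial table (needs `task_level`, `stimulus_duration_ms`);
#'   a `rt_s` column, if present, sets the inter-trial gap (default 1 s).
#' @param params [pupil_params()].
#' @param gain Session gain factor.
#' @return List with `samples` (one data frame, session-clock `t_ms`) and
#'   `events` (the trial table with global `cue_on_ms`, `stim_on_ms`,
#'   `mask_on_ms`, `probe_on_ms` columns).
#' @export
simulate_session_eye <- function(trials, params = pupil_params(), gain = 1) {
  tm <- paradigm_timing()
  n <- nrow(trials)
  rt_ms <- if ("rt_s" %in% names(trials)) round(trials$rt_s * 1000) else rep(1000, n)
  pre_probe <- tm[["cue_ms"]] + trials$stimulus_duration_ms + tm[["mask_ms"]]
  starts <- cumsum(c(0, head(pre_probe + rt_ms, -1)))

  chunks <- vector("list", n)
  for (i in seq_len(n)) {
    chunks[[i]] <- simulate_trial_eye(trials$task_level[i],
                                      trials$stimulus_duration_ms[i],
                                      params, gain, t_offset_ms = starts[i])
  }
  ev <- trials
  ev$cue_on_ms <- starts
  ev$stim_on_ms <- starts + tm[["cue_ms"]]
  ev$mask_on_ms <- starts + tm[["cue_ms"]] + trials$stimulus_duration_ms
  ev$probe_on_ms <- starts + pre_probe
  list(samples = do.call(rbind, chunks), events = ev)
}
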