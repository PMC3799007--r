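# Simulated observers at the deterministic extremes of the psychometric
# model, plus noise-free pupil settings used across test files.

# p = 1 exactly at every ladder duration (lapse 0, saturated logistic)
perfect_observer <- function() {
  observer_params(threshold_ms = rep(1e-6, 4), slope = 8, lapse_rate = 0)
}

# p numerically 0 at every ladder duration (floor ~0, threshold far above)
awful_observer <- function() {
  observer_params(threshold_ms = rep(1e9, 4), slope = 8,
                  guess_floor = c(central = 1e-12, peripheral = 1e-12))
}

# accuracy comfortably above 75% at 24 ms on every level
fast_observer <- function() {
  observer_params(threshold_ms = rep(0.5, 4), slope = 2)
}

quiet_pupil <- function(...) {
  pupil_params(sample_noise_au = 0, blink_rate_hz = 0, saccade_rate_hz = 0,
               gain_jitter_pct = 0, ...)
}

# constant-value, always-valid sample stream holding still gaze
still_samples <- function(n_ms, pupil = 1000, x = 0, y = 0, t0 = 0) {
  data.frame(t_ms = t0 + seq_len(n_ms) - 1, x = rep(x, n_ms), y = rep(y, n_ms),
             pupil_au = rep(pupil, n_ms), valid = rep(1L, n_ms))
}
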