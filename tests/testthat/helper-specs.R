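# Shared fixture builders. Everything is generated in code at test time.

# Minimal quiet spec: one or a few channels, no optional components unless
# switched on explicitly.
quiet_spec <- function(fs_hz = 2000, duration_s = 5, seed = 1,
                       n_rows = 1, n_cols = 1, noise = list(),
                       stimulus = NULL, evoked = NULL, gamma_burst = NULL,
                       oscillation = NULL, spikes = NULL,
                       common_source = NULL, line_noise = NULL) {
  synth_spec(fs_hz = fs_hz, duration_s = duration_s, seed = seed,
             n_rows = n_rows, n_cols = n_cols, noise = noise,
             stimulus = stimulus, evoked = evoked, gamma_burst = gamma_burst,
             oscillation = oscillation, spikes = spikes,
             common_source = common_source, line_noise = line_noise)
}

# Noiseless evoked-only spec on the full grid: the construction oracle for
# delay recovery (injected delays are exactly recoverable).
noiseless_evoked_spec <- function(n_trials = 20, seed = 2, delay_max_s = 0.0057) {
  synth_spec(
    fs_hz = 20000, seed = seed,
    noise = list(white_sd_uv = 0, pink_sd_uv = 0, hash_sd_uv = 0),
    stimulus = list(n_trials = n_trials, train_duration_s = 0.5,
                    pulse_rate_hz = 2, train_period_s = 1, lead_s = 1),
    evoked = list(delay_max_s = delay_max_s),
    gamma_burst = NULL, oscillation = NULL, spikes = NULL,
    common_source = NULL, line_noise = NULL)
}

# A single-channel recording wrapping a given signal vector.
signal_recording <- function(x, fs_hz, n_channels = 1) {
  data <- matrix(rep(x, each = n_channels), nrow = n_channels)
  recording(data, fs_hz, channel_grid(n_rows = n_channels, n_cols = 1))
}

# Hand-built phase field with one field channel and an explicit phase series
# (one frequency per row of `phases`), window centres 1 s apart.
fake_phase_field <- function(phases, freqs_hz = 5, step_s = 1) {
  phases <- matrix(phases, nrow = length(freqs_hz))
  n_win <- ncol(phases)
  structure(list(
    phases = array(phases, c(1, length(freqs_hz), n_win)),
    freqs_hz = freqs_hz, bin_freqs_hz = freqs_hz,
    t_centers_s = seq_len(n_win) * step_s - step_s / 2,
    window_s = step_s, step_s = step_s,
    params = list(), channels = channel_grid(1, 1)),
    class = "oe_phase_field")
}

# Greedy recall/precision of detected vs injected event times.
match_events <- function(true_s, det_s, tol_s = 5e-4) {
  recall <- if (length(true_s))
    mean(vapply(true_s, function(s) any(abs(det_s - s) <= tol_s), logical(1)))
  else NA_real_
  precision <- if (length(det_s))
    mean(vapply(det_s, function(d) any(abs(true_s - d) <= tol_s), logical(1)))
  else NA_real_
  list(recall = recall, precision = precision)
}
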