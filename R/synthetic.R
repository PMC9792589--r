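# Synthetic 16-channel recordings with known ground truth.
#
# The generator emulates the statistical structure the downstream analyses
# assume: stimulus-evoked biphasic LFPs with a linear propagation-delay
# gradient across the grid, evoked gamma bursts, an ongoing theta oscillation,
# MUA spike trains with von Mises phase locking to that oscillation, a shared
# volume-conducted component with identical weight on all channels, 60 Hz
# line noise, 1/f + white background noise, and anesthesia burst-suppression
# epochs with region-specific gamma scaling.

#' Specification for a synthetic recording
#'
#' Returns the default study conditions; any component can be overridden by
#' passing a partial list which is merged into the defaults. Amplitudes are in
#' microvolts, times in seconds, rates in Hz.
#'
#' Defaults mirror the recorded regime: 20 kHz sampling on a 4 x 4 grid with
#' 500 um pitch; 20 trains of 100-ms pulses at 2 Hz for 4 s; evoked responses
#' of ~200 uV at the visual-cortex-proximal corner decaying to ~50 uV at the
#' far corner, 36 ms base latency and 5.7 ms maximal extra delay linear in
#' distance from the reference corner; ~2 Hz spiking locked to a 5 Hz theta
#' oscillation with von Mises concentration kappa = 2; 6 organoid, 8 cortex
#' and 2 ambiguous channels; 1.4 MOhm impedances.
#'
#' @param fs_hz sampling rate.
#' @param duration_s total duration; `NULL` = long enough for the stimulus
#'   protocol plus padding.
#' @param seed integer RNG seed; every generator output is deterministic
#'   given the seed.
#' @param n_rows,n_cols,pitch_um grid geometry.
#' @param noise list: `white_sd_uv` (Gaussian white), `pink_sd_uv` (1/f,
#'   spectral exponent 1), `hash_sd_uv` (Laplace-distributed broadband
#'   "hash", the heavy-tailed background of distant multi-unit activity that
#'   real extracellular recordings show; it also gives each channel's local
#'   background the non-Gaussianity that blind source separation needs to be
#'   identifiable).
#' @param stimulus list: `n_trials`, `pulse_width_s`, `pulse_rate_hz`,
#'   `train_duration_s`, `train_period_s`, `lead_s`; or `NULL` for none.
#' @param evoked list: `amp_ref_uv`, `amp_far_uv`, `latency0_s`,
#'   `delay_max_s`, `neg_width_s`, `pos_width_s`, `pos_frac`; or `NULL`.
#' @param gamma_burst list: `freq_hz`, `amp_uv`, `duration_s`; or `NULL`.
#' @param oscillation list: `freq_hz`, `amp_uv` (scalar: amplitude at the
#'   reference corner, decaying to `far_frac` of it at the far corner, so the
#'   rhythm is locally generated rather than uniform; or a per-channel
#'   vector); or `NULL`.
#' @param spikes list: `rate_hz`, `amp_sd` (MUA-band peak in units of the
#'   channel's MUA-band noise sd, calibrated after band-pass filtering),
#'   `amp_uv` (absolute fallback used when the noise is zero),
#'   `lock_freq_hz`, `kappa` (scalar or per channel), `mu`, `stim_gated`
#'   (default `TRUE`: with a stimulus present, `kappa` applies only inside
#'   `[onset, onset + width + stim_pad_s)` and `kappa_no_stim` elsewhere),
#'   `evoked_rate_hz` (additional multi-unit firing during light pulses,
#'   phase-locked like the stimulated condition; drives the evoked MUA
#'   power response); or `NULL`.
#' @param common_source list: `amp_uv` (sd of the shared trace), `rate_hz`
#'   (transient rate), `width_s` (typical transient width); or `NULL`.
#' @param line_noise list: `freq_hz`, `amp_uv`; or `NULL`.
#' @param anesthesia list used by [generate_anesthesia_epoch()]:
#'   `duration_s`, `suppression_fraction`, `mean_cycle_s`, `pink_sd_uv`,
#'   `gamma_freqs_hz`, `gamma_amp_uv`, `gamma_power_scale`, `sensor_sd_uv`.
#' @param regions optional character vector of per-channel region labels;
#'   `NULL` = default assignment (6 organoid nearest the far corner, 8 cortex
#'   nearest the reference corner, 2 ambiguous).
#' @param impedance_ohm per-channel impedances (recycled).
#' @return object of class `oe_synth_spec`.
#' @export
synth_spec <- function(fs_hz = 20000, duration_s = NULL, seed = 1L,
                       n_rows = 4, n_cols = 4, pitch_um = 500,
                       noise = list(), stimulus = list(), evoked = list(),
                       gamma_burst = list(), oscillation = list(),
                       spikes = list(), common_source = list(),
                       line_noise = list(), anesthesia = list(),
                       regions = NULL, impedance_ohm = 1.4e6) {
  merge <- function(defaults, user) {
    if (is.null(user)) return(NULL)
    utils::modifyList(defaults, user)
  }
  spec <- list(
    fs_hz = fs_hz, duration_s = duration_s, seed = as.integer(seed),
    n_rows = n_rows, n_cols = n_cols, pitch_um = pitch_um,
    noise = merge(list(white_sd_uv = 4, pink_sd_uv = 4, hash_sd_uv = 4),
                  noise),
    stimulus = merge(list(n_trials = 20, pulse_width_s = 0.1,
                          pulse_rate_hz = 2, train_duration_s = 4,
                          train_period_s = 6.1, lead_s = 2), stimulus),
    evoked = merge(list(amp_ref_uv = 200, amp_far_uv = 50,
                        latency0_s = 0.036, delay_max_s = 0.0057,
                        neg_width_s = 0.008, pos_width_s = 0.015,
                        pos_frac = 0.6), evoked),
    gamma_burst = merge(list(freq_hz = 80, amp_uv = 10, duration_s = 0.15),
                        gamma_burst),
    oscillation = merge(list(freq_hz = 5, amp_uv = 25, far_frac = 0.3),
                        oscillation),
    spikes = merge(list(rate_hz = 2, amp_sd = 6, amp_uv = 10,
                        lock_freq_hz = 5, kappa = 2, mu = pi,
                        kappa_no_stim = 0, stim_gated = TRUE,
                        stim_pad_s = 0.1, evoked_rate_hz = 60), spikes),
    common_source = merge(list(amp_uv = 15, rate_hz = 0.5, width_s = 0.12),
                          common_source),
    line_noise = merge(list(freq_hz = 60, amp_uv = 5), line_noise),
    anesthesia = merge(list(duration_s = 60, suppression_fraction = 0.5,
                            mean_cycle_s = 4, pink_sd_uv = 15,
                            gamma_freqs_hz = c(45, 80), gamma_amp_uv = 25,
                            gamma_power_scale = 0.5, sensor_sd_uv = 1),
                       anesthesia),
    regions = regions, impedance_ohm = impedance_ohm
  )
  sp <- spec$spikes
  if (!is.null(sp)) {
    if (any(sp$kappa < 0)) stopf("kappa must be >= 0")
    if (sp$rate_hz < 0) stopf("spike rate must be >= 0")
  }
  structure(spec, class = "oe_synth_spec")
}

#' Expected phase-locking value of a von Mises distribution
#'
#' The mean resultant length of von Mises(mu, kappa) is the Bessel-function
#' ratio I1(kappa)/I0(kappa); this is the population value the PLV estimator
#' recovers for phase-locked spikes. Monotone increasing from 0 (kappa = 0,
#' uniform phases) to 1 (kappa -> Inf, point mass).
#'
#' @param kappa von Mises concentration, >= 0 (vectorized).
#' @return expected PLV in `[0, 1]`.
#' @export
expected_plv <- function(kappa) {
  if (any(!is.finite(kappa)) || any(kappa < 0))
    stopf("kappa must be finite and >= 0")
  out <- numeric(length(kappa))
  big <- kappa > 1e5   # beyond besselI's reliable range: asymptotic expansion
  out[big] <- 1 - 1 / (2 * kappa[big]) - 1 / (8 * kappa[big]^2)
  k <- kappa[!big]     # exponentially scaled ratio is stable elsewhere
  out[!big] <- ifelse(k == 0, 0,
    besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE))
  out
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` yields the circular uniform.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration, >= 0.
#' @return angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stopf("kappa must be >= 0")
  if (n == 0) return(numeric(0))
  if (kappa == 0) {
    th <- stats::runif(n, -pi, pi)
    return(th)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling(1.3 * (n - length(out))))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, sign(u3[ok] - 0.5) * acos(pmax(-1, pmin(1, f[ok]))))
  }
  th <- (mu + out[seq_len(n)] + pi) %% (2 * pi) - pi
  th
}

#' Poisson spike times phase-locked to an oscillation
#'
#' Spike count is Poisson(rate x duration); each spike is placed in a
#' uniformly chosen cycle of the `lock_freq_hz` oscillation at a phase drawn
#' from von Mises(`mu`, `kappa`), where the oscillation's instantaneous phase
#' at time t is `2*pi*lock_freq_hz*t` (phase 0 = cosine peak). Events closer
#' than `min_isi_s` are thinned to the earlier one.
#'
#' @param rate_hz mean firing rate (> 0).
#' @param duration_s recording duration (> 0).
#' @param lock_freq_hz frequency of the locking oscillation.
#' @param kappa von Mises concentration (0 = no locking).
#' @param mu preferred phase (radians); default `pi`, the oscillation trough.
#' @param seed optional RNG seed.
#' @param min_isi_s minimal inter-event interval.
#' @return sorted spike times in seconds.
#' @export
sample_locked_spikes <- function(rate_hz, duration_s, lock_freq_hz = 5,
                                 kappa = 0, mu = pi, seed = NULL,
                                 min_isi_s = 0.0015) {
  assert_scalar_num(rate_hz, "rate_hz", lo = 1e-12)
  assert_scalar_num(duration_s, "duration_s", lo = 1e-12)
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1, rate_hz * duration_s)
  if (n == 0) return(numeric(0))
  n_cycles <- max(1L, floor(duration_s * lock_freq_hz))
  cyc <- sample.int(n_cycles, n, replace = TRUE) - 1L
  ph <- rvonmises(n, mu = mu, kappa = kappa) %% (2 * pi)
  tt <- sort((cyc + ph / (2 * pi)) / lock_freq_hz)
  tt <- tt[tt < duration_s]
  if (length(tt) > 1) {
    keep <- c(TRUE, diff(tt) >= min_isi_s)
    # iterate: thinning can create new short gaps only backwards, one pass
    # relative to the kept predecessor is required
    while (any(!keep)) {
      tt <- tt[keep]
      if (length(tt) < 2) break
      keep <- c(TRUE, diff(tt) >= min_isi_s)
    }
  }
  tt
}

# 1/f ("pink", spectral exponent 1) Gaussian noise with the requested sd.
pink_noise <- function(n, sd = 1) {
  if (sd == 0) return(numeric(n))
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))          # avoid DC blow-up
  f <- pmin(f, n - f + 1)            # symmetric |frequency| index
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x * sd / stats::sd(x)
}

# Biphasic evoked-LFP kernel sampled at fs, circularly shifted so the global
# minimum sits exactly at index `peak_at` (1-based). Negative lobe of width
# sigma_n followed by a positive lobe.
biphasic_lfp_kernel <- function(fs, neg_width_s, pos_width_s, pos_frac) {
  span <- 4 * neg_width_s + 6 * pos_width_s
  tau <- seq(-span, span, by = 1 / fs)
  delta <- 1.5 * (neg_width_s + pos_width_s)
  k <- -exp(-tau^2 / (2 * neg_width_s^2)) +
    pos_frac * exp(-(tau - delta)^2 / (2 * pos_width_s^2))
  list(kernel = k, peak_at = which.min(k))
}

# Biphasic extracellular spike kernel: 0.4 ms negative lobe then 0.6 ms
# positive lobe (energy inside the 0.5-3 kHz MUA band). Peak value -1.
biphasic_spike_kernel <- function(fs, neg_ms = 0.4, pos_ms = 0.6) {
  n_neg <- max(2L, round(neg_ms / 1000 * fs))
  n_pos <- max(2L, round(pos_ms / 1000 * fs))
  k <- c(-sin(pi * seq_len(n_neg) / (n_neg + 1)),
         (neg_ms / pos_ms) * sin(pi * seq_len(n_pos) / (n_pos + 1)))
  list(kernel = k, peak_at = which.min(k))
}

# Add `kernel` (index `peak_at` aligned to each 1-based sample index in
# `ats`, scaled by `amp`) into the vector `v`; clips at edges. Operates on a
# channel-local vector so the additions stay in place.
add_kernels <- function(v, kernel, peak_at, ats, amp) {
  n <- length(v)
  base <- seq_along(kernel) - peak_at
  for (a in ats) {
    idx <- base + a
    ok <- idx >= 1L & idx <= n
    if (all(ok)) v[idx] <- v[idx] + amp * kernel
    else if (any(ok)) v[idx[ok]] <- v[idx[ok]] + amp * kernel[ok]
  }
  v
}

# Default region assignment: the 6 channels nearest the organoid corner
# (row 0, col 0) are organoid, then the 8 nearest the reference corner
# (visual-cortex-proximal, opposite corner) are cortex, the rest ambiguous.
default_regions <- function(ch, n_organoid = 6, n_cortex = 8) {
  d_org <- sqrt(ch$x_um^2 + ch$y_um^2)
  ref <- c(max(ch$x_um), max(ch$y_um))
  d_ref <- sqrt((ch$x_um - ref[1])^2 + (ch$y_um - ref[2])^2)
  region <- rep("ambiguous", nrow(ch))
  org <- order(d_org, ch$channel_id)[seq_len(min(n_organoid, nrow(ch)))]
  region[org] <- "organoid"
  rest <- setdiff(order(d_ref, ch$channel_id), org)
  region[rest[seq_len(min(n_cortex, length(rest)))]] <- "cortex"
  region
}

# Distances (um) from the reference (visual-cortex-proximal) corner channel.
ref_corner_distance <- function(ch) {
  ref <- c(max(ch$x_um), max(ch$y_um))
  sqrt((ch$x_um - ref[1])^2 + (ch$y_um - ref[2])^2)
}

#' Generate a synthetic multichannel recording with ground truth
#'
#' Deterministic given `spec$seed`. Returns both the recording and the
#' injected parameters (delays, spike times, true PLV per channel, the shared
#' source trace, evoked amplitudes) for recovery tests.
#'
#' The evoked biphasic LFP of channel i peaks (negative) at
#' `latency0_s + delay_i` after each pulse onset, with
#' `delay_i = delay_max_s * dist_i / max(dist)` where `dist_i` is the
#' Euclidean distance from the reference corner channel. Evoked amplitude
#' decays linearly in that distance from `amp_ref_uv` to `amp_far_uv`. Spike
#' kernels are scaled so their MUA-band peak is `amp_sd` times the channel's
#' MUA-band background-noise sd. The shared component and line noise are
#' added with identical weight to every channel.
#'
#' @param spec an [synth_spec()].
#' @return list with elements `recording` (an [recording()]) and `truth`
#'   (list: `true_delays_s`, `evoked_amp_uv`, `spike_times_s`, `true_plv`,
#'   `common_source_trace`, `oscillation`, `spike_kernel`).
#' @export
generate_recording <- function(spec) {
  if (!inherits(spec, "oe_synth_spec")) stopf("spec must be an oe_synth_spec")
  fs <- spec$fs_hz
  set.seed(spec$seed)

  stim <- NULL
  stim_onsets <- numeric(0)
  if (!is.null(spec$stimulus)) {
    st <- spec$stimulus
    n_pulses <- max(1L, round(st$train_duration_s * st$pulse_rate_hz))
    train_starts <- st$lead_s + (seq_len(st$n_trials) - 1) * st$train_period_s
    stim_onsets <- as.vector(vapply(train_starts, function(t0)
      t0 + (seq_len(n_pulses) - 1) / st$pulse_rate_hz, numeric(n_pulses)))
    stim <- stimulus_protocol(stim_onsets, st$pulse_width_s, st$pulse_rate_hz,
                              st$train_duration_s, st$n_trials)
  }
  duration <- spec$duration_s %||% (if (length(stim_onsets))
    max(stim_onsets) + 1 / (stim$pulse_rate_hz) + 1 else 10)
  if (!is.null(stim) &&
      duration < spec$stimulus$lead_s + spec$stimulus$train_duration_s)
    stopf("duration_s (%g s) too short to contain one stimulus train", duration)

  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  ch <- channel_grid(spec$n_rows, spec$n_cols, spec$pitch_um,
                     region = spec$regions %||% "cortex",
                     impedance_ohm = spec$impedance_ohm)
  if (is.null(spec$regions)) ch$region <- default_regions(ch)
  n_ch <- nrow(ch)
  x <- matrix(0, n_ch, n)

  # --- background noise (white + 1/f), per channel -------------------------
  no <- spec$noise
  hash_sd <- no$hash_sd_uv %||% 0
  noisy <- !is.null(no) &&
    (no$white_sd_uv > 0 || no$pink_sd_uv > 0 || hash_sd > 0)
  if (noisy) {
    for (i in seq_len(n_ch)) {
      x[i, ] <- x[i, ] + stats::rnorm(n, sd = no$white_sd_uv) +
        pink_noise(n, sd = no$pink_sd_uv)
      if (hash_sd > 0)   # Laplace(0, b), sd = b*sqrt(2)
        x[i, ] <- x[i, ] + sample(c(-1, 1), n, replace = TRUE) *
          stats::rexp(n, rate = sqrt(2) / hash_sd)
    }
  }

  # channel MUA-band noise sd: scale reference for injected spikes
  sd_mua <- rep(0, n_ch)
  if (noisy && !is.null(spec$spikes) && fs >= 8000) {
    flt <- mua_filter(fs)
    for (i in seq_len(n_ch)) sd_mua[i] <- stats::sd(signal::filtfilt(flt, x[i, ]))
  }

  # --- evoked biphasic LFP with delay/amplitude gradients ------------------
  dist_um <- ref_corner_distance(ch)
  true_delays <- rep(0, n_ch)
  evoked_amp <- rep(0, n_ch)
  if (!is.null(spec$evoked) && length(stim_onsets)) {
    ev <- spec$evoked
    d_max <- max(dist_um)
    true_delays <- if (d_max > 0) ev$delay_max_s * dist_um / d_max else rep(0, n_ch)
    evoked_amp <- ev$amp_ref_uv +
      (ev$amp_far_uv - ev$amp_ref_uv) * (if (d_max > 0) dist_um / d_max else 0)
    kk <- biphasic_lfp_kernel(fs, ev$neg_width_s, ev$pos_width_s, ev$pos_frac)
    for (i in seq_len(n_ch)) {
      at <- round((stim_onsets + ev$latency0_s + true_delays[i]) * fs) + 1L
      x[i, ] <- add_kernels(x[i, ], kk$kernel, kk$peak_at, at, evoked_amp[i])
    }
  }

  # --- evoked (induced) gamma bursts at pulse onsets -----------------------
  # Induced, not phase-locked: the carrier phase is random per pulse, so the
  # burst contributes power to single-trial spectrograms but averages toward
  # zero in the trial-averaged waveform (and cannot bias evoked peak maps).
  # Its amplitude follows the evoked spatial gradient (a local response).
  if (!is.null(spec$gamma_burst) && length(stim_onsets) &&
      spec$gamma_burst$amp_uv > 0) {
    gb <- spec$gamma_burst
    nb <- round(gb$duration_s * fs)
    env <- 0.5 * (1 - cos(2 * pi * seq_len(nb) / (nb + 1)))
    tau <- (seq_len(nb) - 1) / fs
    rel <- if (any(evoked_amp > 0)) evoked_amp / max(evoked_amp) else rep(1, n_ch)
    for (on in stim_onsets) {
      burst <- env * sin(2 * pi * gb$freq_hz * tau + stats::runif(1, 0, 2 * pi))
      i0 <- round(on * fs) + 1L
      idx <- i0:min(n, i0 + nb - 1L)
      x[, idx] <- x[, idx] + (gb$amp_uv * rel) %o% burst[seq_along(idx)]
    }
  }

  # --- ongoing oscillation (phase 0 = cosine peak at t = 0) ----------------
  # Locally generated rhythm: by default its amplitude decays linearly with
  # distance from the visual-cortex-proximal corner (to `far_frac` of the
  # reference amplitude), so it is not mistaken for a volume-conducted
  # (uniform) component and the spatial phase-locking map has structure.
  osc_amp <- rep(0, n_ch)
  if (!is.null(spec$oscillation) && any(spec$oscillation$amp_uv > 0)) {
    os <- spec$oscillation
    if (length(os$amp_uv) == 1) {
      far <- os$far_frac %||% 0.3
      d <- ref_corner_distance(ch)
      rel <- if (max(d) > 0) d / max(d) else 0
      osc_amp <- os$amp_uv * (1 - (1 - far) * rel)
    } else {
      osc_amp <- rep_len(os$amp_uv, n_ch)
    }
    carrier <- cos(2 * pi * os$freq_hz * t)
    x <- x + osc_amp %o% carrier
  }

  # --- phase-locked spike trains -------------------------------------------
  spike_times <- vector("list", n_ch)
  true_plv <- rep(NA_real_, n_ch)
  spk_kernel <- NULL
  if (!is.null(spec$spikes) && spec$spikes$rate_hz > 0) {
    sp <- spec$spikes
    kap <- rep_len(sp$kappa, n_ch)
    true_plv <- expected_plv(kap)
    kk <- biphasic_spike_kernel(fs)
    spk_kernel <- kk$kernel
    # amplitudes are stated in MUA-band units: calibrate for the band-pass
    # attenuation so the filtered spike peak equals amp_sd x the band sd
    att <- 1
    if (fs >= 8000) {
      pad <- numeric(round(0.05 * fs))
      att <- abs(min(signal::filtfilt(mua_filter(fs), c(pad, kk$kernel, pad))))
    }
    # stimulus-gated locking: with a stimulus present (and stim_gated, the
    # default), spikes inside [onset, onset + width + stim_pad_s) lock at
    # kappa while spikes elsewhere lock at kappa_no_stim (default 0) - the
    # contrast the stim/no-stim comparison is designed to detect.
    gated <- (sp$stim_gated %||% TRUE) && length(stim_onsets) > 0
    kap0 <- rep_len(sp$kappa_no_stim %||% 0, n_ch)
    pad <- sp$stim_pad_s %||% 0.1
    in_stim <- function(tt) {
      j <- findInterval(tt, stim_onsets)
      j >= 1 & (tt - stim_onsets[pmax(1, j)]) < spec$stimulus$pulse_width_s + pad
    }
    in_pulse <- function(tt) {
      j <- findInterval(tt, stim_onsets)
      j >= 1 & (tt - stim_onsets[pmax(1, j)]) < spec$stimulus$pulse_width_s
    }
    evoked_rate <- sp$evoked_rate_hz %||% 0
    for (i in seq_len(n_ch)) {
      if (gated) {
        t_lock <- sample_locked_spikes(sp$rate_hz, duration, sp$lock_freq_hz,
                                       kappa = kap[i], mu = sp$mu)
        t_rest <- sample_locked_spikes(sp$rate_hz, duration, sp$lock_freq_hz,
                                       kappa = kap0[i], mu = sp$mu)
        tt <- sort(c(t_lock[in_stim(t_lock)], t_rest[!in_stim(t_rest)]))
        if (evoked_rate > 0) {
          # evoked multi-unit burst: extra locked firing during each pulse
          t_ev <- sample_locked_spikes(evoked_rate, duration, sp$lock_freq_hz,
                                       kappa = kap[i], mu = sp$mu)
          tt <- sort(c(tt, t_ev[in_pulse(t_ev)]))
        }
        if (length(tt) > 1) tt <- tt[c(TRUE, diff(tt) >= 0.0015)]
      } else {
        tt <- sample_locked_spikes(sp$rate_hz, duration, sp$lock_freq_hz,
                                   kappa = kap[i], mu = sp$mu)
      }
      spike_times[[i]] <- tt
      amp <- (if (sd_mua[i] > 0) sp$amp_sd * sd_mua[i] else sp$amp_uv) / att
      x[i, ] <- add_kernels(x[i, ], kk$kernel, kk$peak_at,
                            round(tt * fs) + 1L, amp)
    }
  }

  # --- shared (volume-conducted) component, identical weight ---------------
  # Modeled on awake-motion artifacts: a sparse Poisson train of signed
  # raised-cosine transients. Sparse transients are both what shared
  # artifacts look like in awake recordings and a source with strong
  # LFP-timescale kurtosis, which fourth-order blind source separation needs
  # in order to isolate the shared component from the Gaussian background.
  common_trace <- numeric(0)
  if (!is.null(spec$common_source) && spec$common_source$amp_uv > 0) {
    cs <- spec$common_source
    rate <- cs$rate_hz %||% 0.5
    width <- cs$width_s %||% 0.12
    n_ev <- stats::rpois(1, rate * duration)
    raw <- numeric(n)
    if (n_ev > 0) {
      at <- round(stats::runif(n_ev, 0, duration) * fs) + 1L
      amps <- sample(c(-1, 1), n_ev, replace = TRUE) * stats::rexp(n_ev)
      for (k in seq_len(n_ev)) {
        nb <- max(4L, round(width * stats::runif(1, 0.5, 1.5) * fs))
        bump <- 0.5 * (1 - cos(2 * pi * seq_len(nb) / (nb + 1)))
        raw <- add_kernels(raw, bump, as.integer(nb / 2), at[k], amps[k])
      }
    }
    if (stats::sd(raw) > 0) {
      common_trace <- raw * cs$amp_uv / stats::sd(raw)
      x <- x + rep(common_trace, each = n_ch)
    }
  }

  # --- line noise, identical on all channels -------------------------------
  if (!is.null(spec$line_noise) && spec$line_noise$amp_uv > 0) {
    ln <- spec$line_noise
    x <- x + rep(ln$amp_uv * sin(2 * pi * ln$freq_hz * t), each = n_ch)
  }

  rec <- recording(x, fs, ch, stimulus = stim, state = "awake",
                   provenance = sprintf("synthetic recording (seed %d)", spec$seed))
  truth <- list(
    true_delays_s = true_delays,
    evoked_amp_uv = evoked_amp,
    evoked_latency_s = if (is.null(spec$evoked)) NULL else
      spec$evoked$latency0_s + true_delays,
    spike_times_s = spike_times,
    true_plv = true_plv,
    common_source_trace = common_trace,
    oscillation = spec$oscillation,
    osc_amp_uv = osc_amp,
    sd_mua_uv = sd_mua,
    spike_kernel = spk_kernel
  )
  list(recording = rec, truth = truth)
}

#' Generate a spontaneous-activity epoch (awake or under anesthesia)
#'
#' Anesthetized epochs show burst suppression: alternating segments of
#' high-amplitude broadband activity and near-silence. Segment lengths are
#' whole seconds (suppression and burst lengths drawn with means
#' `mean_cycle_s * suppression_fraction` and `mean_cycle_s * (1 -
#' suppression_fraction)`), the envelope has 10-ms raised-cosine ramps and a
#' 2% floor. Burst content is per-channel 1/f noise plus narrowband gamma
#' components; on organoid-labeled channels the gamma amplitude is scaled by
#' `sqrt(gamma_power_scale)` so gamma band power scales by
#' `gamma_power_scale`. Awake epochs use the same content with envelope 1 and
#' no gamma scaling.
#'
#' @param spec an [synth_spec()]; the `anesthesia` block supplies parameters.
#' @param state `"anesthetized"` (default) or `"awake"`.
#' @return list with `recording` and `truth` (realized suppression fraction,
#'   gamma scale, segment table).
#' @export
generate_anesthesia_epoch <- function(spec,
                                      state = c("anesthetized", "awake")) {
  if (!inherits(spec, "oe_synth_spec")) stopf("spec must be an oe_synth_spec")
  state <- match.arg(state)
  an <- spec$anesthesia
  if (is.null(an)) stopf("spec$anesthesia block is not set")
  fs <- spec$fs_hz
  set.seed(spec$seed + (state == "awake"))
  duration <- an$duration_s
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs

  ch <- channel_grid(spec$n_rows, spec$n_cols, spec$pitch_um,
                     region = spec$regions %||% "cortex",
                     impedance_ohm = spec$impedance_ohm)
  if (is.null(spec$regions)) ch$region <- default_regions(ch)
  n_ch <- nrow(ch)

  # --- burst-suppression envelope ------------------------------------------
  env <- rep(1, n)
  segments <- data.frame()
  supp_frac_real <- 0
  if (state == "anesthetized") {
    frac <- an$suppression_fraction
    mean_supp <- max(1, an$mean_cycle_s * frac)
    mean_burst <- max(1, an$mean_cycle_s * (1 - frac))
    lens <- c(); kinds <- c(); total <- 0; burst <- TRUE
    while (total < duration) {
      m <- if (burst) mean_burst else mean_supp
      len <- 1 + stats::rpois(1, max(0, m - 1))
      lens <- c(lens, len); kinds <- c(kinds, if (burst) "burst" else "suppression")
      total <- total + len
      burst <- !burst
    }
    segments <- data.frame(kind = kinds, start_s = cumsum(c(0, lens[-length(lens)])),
                           duration_s = lens)
    env <- rep(0.02, n)
    for (k in seq_len(nrow(segments))) {
      if (segments$kind[k] != "burst") next
      i0 <- round(segments$start_s[k] * fs) + 1L
      i1 <- min(n, round((segments$start_s[k] + segments$duration_s[k]) * fs))
      if (i0 <= n) env[i0:i1] <- 1
    }
    ramp <- round(0.01 * fs)
    if (ramp > 1) {
      w <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
      env <- stats::filter(env, rep(1 / ramp, ramp), sides = 2)
      env[is.na(env)] <- 0.02
      env <- as.numeric(env)
    }
    supp <- segments$kind == "suppression"
    supp_frac_real <- sum(pmin(segments$duration_s[supp],
                               pmax(0, duration - segments$start_s[supp]))) / duration
  }

  gamma_scale <- if (state == "anesthetized") an$gamma_power_scale else 1
  x <- matrix(0, n_ch, n)
  for (i in seq_len(n_ch)) {
    sig <- pink_noise(n, sd = an$pink_sd_uv)
    g_amp <- an$gamma_amp_uv * stats::runif(1, 0.9, 1.1)
    if (ch$region[i] == "organoid") g_amp <- g_amp * sqrt(gamma_scale)
    for (gf in an$gamma_freqs_hz)
      sig <- sig + g_amp * sin(2 * pi * gf * t + stats::runif(1, 0, 2 * pi))
    x[i, ] <- sig * env + stats::rnorm(n, sd = an$sensor_sd_uv)
  }

  rec <- recording(x, fs, ch, stimulus = NULL, state = state,
                   provenance = sprintf("synthetic %s epoch (seed %d)",
                                        state, spec$seed))
  truth <- list(suppression_fraction = supp_frac_real,
                gamma_power_scale = gamma_scale,
                gamma_freqs_hz = an$gamma_freqs_hz,
                segments = segments)
  list(recording = rec, truth = truth)
}
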