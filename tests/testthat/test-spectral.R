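test_that("Morlet power localizes tones, scales quadratically, concentrates energy", {
  fs <- 500
  t <- (0:(fs * 30 - 1)) / fs
  grid <- exp(seq(log(2), log(100), length.out = 50))
  rec <- signal_recording(sin(2 * pi * 10 * t), fs)
  tfa <- morlet_spectrogram(rec, freqs_hz = grid)
  pw <- apply(tfa$values[1, , ], 1, mean)
  expect_lt(abs(grid[which.max(pw)] - 10), 0.5)
  # quadratic amplitude scaling
  tfa2 <- morlet_spectrogram(signal_recording(2 * sin(2 * pi * 10 * t), fs),
                             freqs_hz = grid)
  expect_equal(apply(tfa2$values[1, , ], 1, mean), 4 * pw, tolerance = 1e-10)
  # >= 90% of the tone's total power within one wavelet bandwidth (FWHM of
  # the power response, 1.665 * f0/n_cycles) of 10 Hz, on a linear grid so
  # the sum approximates the frequency integral
  lin <- seq(2, 50, by = 0.5)
  pwl <- apply(morlet_spectrogram(rec, freqs_hz = lin)$values[1, , ], 1, mean)
  bw <- 2 * sqrt(log(2)) * 10 / 7
  expect_gte(sum(pwl[abs(lin - 10) <= bw]) / sum(pwl), 0.9)
  # zero signal, zero power; Nyquist guard
  expect_equal(max(morlet_spectrogram(signal_recording(numeric(fs), fs),
                                      freqs_hz = c(5, 10))$values), 0)
  expect_error(morlet_spectrogram(rec, freqs_hz = c(10, 300)), "Nyquist")
})

test_that("band power is flat for white noise, additive, and tone-dominated", {
  set.seed(3)
  fs <- 500
  rec <- signal_recording(rnorm(fs * 60), fs)
  bp <- band_power(morlet_spectrogram(rec))
  dens <- bp[1, ] / mean(bp[1, ])
  expect_true(all(abs(dens - 1) < 0.2))   # per-Hz density ~ flat
  # theta tone dwarfs all other bands
  t <- (0:(fs * 30 - 1)) / fs
  bt <- band_power(morlet_spectrogram(signal_recording(
    20 * sin(2 * pi * 6 * t), fs)))
  expect_true(all(bt[1, "theta"] > 20 * bt[1, colnames(bt) != "theta"]))
  expect_error(band_power(morlet_spectrogram(rec),
                          data.frame(name = "x", lo_hz = 200, hi_hz = 210)),
               "no grid")
})

test_that("trial-averaged spectrograms equal single-trial for identical trials and
           are invariant to per-trial phase randomization", {
  g <- generate_recording(noiseless_evoked_spec(n_trials = 4, seed = 6))
  dec <- decimate_recording(filter_lfp(g$recording), 500)
  tt <- epoch_trials(dec, pre_s = 0.1, post_s = 0.3)
  grid <- seq(8, 100, by = 4)
  tas <- trial_averaged_spectrogram(tt, freqs_hz = grid)
  one <- tt; one$values <- tt$values[1, , , drop = FALSE]; one$n_trials <- 1L
  tas1 <- trial_averaged_spectrogram(one, freqs_hz = grid)
  expect_equal(tas$values, tas1$values, tolerance = 1e-5)  # identical trials

  # tone trials with random phase per trial: same averaged power as aligned
  set.seed(8)
  fs <- 500; n_t <- 200; n_tr <- 40
  mk <- function(random_phase) {
    v <- array(0, c(n_tr, 1, n_t))
    for (k in seq_len(n_tr)) {
      ph <- if (random_phase) runif(1, 0, 2 * pi) else 0
      v[k, 1, ] <- sin(2 * pi * 20 * (0:(n_t - 1)) / fs + ph)
    }
    structure(list(values = v, t_axis_s = (0:(n_t - 1)) / fs,
                   baseline_window_s = c(-0.1, 0), n_trials = n_tr,
                   fs_hz = fs, channels = channel_grid(1, 1),
                   onsets_s = numeric(n_tr)), class = "oe_trials")
  }
  p_fix <- trial_averaged_spectrogram(mk(FALSE), freqs_hz = c(15, 20, 25))
  p_rnd <- trial_averaged_spectrogram(mk(TRUE), freqs_hz = c(15, 20, 25))
  expect_equal(mean(p_rnd$values[1, 2, ]), mean(p_fix$values[1, 2, ]),
               tolerance = 0.02)
})

test_that("region power ratio is unity for copies, scale-invariant, and guarded", {
  set.seed(4)
  fs <- 500
  n <- fs * 30
  ch <- channel_grid(2, 2, region = c("organoid", "organoid", "cortex", "cortex"))
  base <- matrix(rnorm(2 * n), 2, n)
  rec <- recording(rbind(base, base), fs, ch)   # organoid = copies of cortex
  bp <- band_power(morlet_spectrogram(rec, freqs_hz = seq(2, 100, by = 4)))
  rr <- region_power_ratio(bp, ch)
  expect_equal(rr$organoid_ratio, rep(1, nrow(rr)), tolerance = 1e-10)
  expect_true(all(abs(rr$p_value - 0.5) < 1e-6))
  # multiplying every channel by a constant changes nothing
  rr2 <- region_power_ratio(9 * bp, ch)
  expect_equal(rr2$organoid_ratio, rr$organoid_ratio)
  expect_equal(rr2$p_value, rr$p_value)
  ch1 <- channel_grid(2, 2, region = c("organoid", rep("cortex", 3)))
  expect_error(region_power_ratio(bp, ch1), ">= 2")
})
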