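test_that("expected_plv matches an independent Bessel-quadrature oracle", {
  expect_identical(expected_plv(0), 0)
  expect_lt(abs(expected_plv(1e6) - 1), 1e-3)
  # independent oracle: mean resultant length by direct numerical quadrature
  # of the von Mises density, no Bessel functions involved
  vm_resultant <- function(kappa) {
    z <- stats::integrate(function(th) exp(kappa * cos(th)), -pi, pi)$value
    stats::integrate(function(th) cos(th) * exp(kappa * cos(th)), -pi, pi)$value / z
  }
  for (k in c(0.5, 2, 5))
    expect_equal(expected_plv(k), vm_resultant(k), tolerance = 1e-8)
  kk <- seq(0, 10, by = 0.5)
  expect_true(all(diff(expected_plv(kk)) > 0))
  expect_error(expected_plv(-1), "kappa")
})

test_that("phase-locked spike sampling produces von Mises phases at the right rate", {
  set.seed(42)
  # kappa = 0: resultant below the Rayleigh noise level
  tt <- sample_locked_spikes(2, 100, 5, kappa = 0, seed = 7)
  ph <- (2 * pi * 5 * tt) %% (2 * pi)
  expect_lt(plv(ph), 1.5 / sqrt(length(tt)))
  # near-degenerate concentration: all phases at mu
  tt <- sample_locked_spikes(5, 50, 5, kappa = 1e6, seed = 8)
  ph <- (2 * pi * 5 * tt) %% (2 * pi)
  expect_true(all(abs(ph - pi) < 0.011))
  # kappa = 2 at n ~ 1000: empirical resultant near the Bessel value
  tt <- sample_locked_spikes(10, 100, 5, kappa = 2, seed = 9)
  ph <- (2 * pi * 5 * tt) %% (2 * pi)
  expect_lt(abs(plv(ph) - expected_plv(2)), 0.04)
  # Poisson count within sampling error; ordered times; ISI floor respected
  expect_lt(abs(length(tt) - 1000), 4 * sqrt(1000))
  expect_true(all(diff(tt) >= 0.0015))
})

test_that("generator is deterministic and recovers injected structure when noiseless", {
  spec <- quiet_spec(fs_hz = 4000, duration_s = 3, seed = 5,
                     noise = list(white_sd_uv = 2, pink_sd_uv = 2, hash_sd_uv = 2),
                     oscillation = list(freq_hz = 5, amp_uv = 10),
                     common_source = list(amp_uv = 8))
  g1 <- generate_recording(spec)
  g2 <- generate_recording(spec)
  expect_identical(g1$recording$data, g2$recording$data)
  expect_identical(g1$truth$spike_times_s, g2$truth$spike_times_s)

  # noiseless single channel, one pulse: trace minimum exactly at latency0
  sp1 <- synth_spec(fs_hz = 20000, seed = 1, n_rows = 1, n_cols = 1,
                    noise = list(white_sd_uv = 0, pink_sd_uv = 0, hash_sd_uv = 0),
                    stimulus = list(n_trials = 1, train_duration_s = 0.5,
                                    pulse_rate_hz = 2, train_period_s = 1,
                                    lead_s = 0.5),
                    gamma_burst = NULL, oscillation = NULL, spikes = NULL,
                    common_source = NULL, line_noise = NULL)
  g <- generate_recording(sp1)
  onset <- g$recording$stimulus$onsets_s[1]
  t_min <- (which.min(g$recording$data[1, ]) - 1) / 20000
  expect_lt(abs(t_min - (onset + 0.036)), 1 / 20000 + 1e-12)

  # full grid: per-channel peak-delay differences equal the injected gradient
  gg <- generate_recording(noiseless_evoked_spec(n_trials = 2))
  rec <- gg$recording
  onset <- rec$stimulus$onsets_s[1]
  i0 <- round(onset * 20000)
  win <- i0 + seq(round(0.01 * 20000), round(0.08 * 20000))
  delays <- apply(rec$data[, win], 1, which.min) / 20000
  rel <- delays - delays[16]          # channel 16 = reference corner
  expect_true(all(abs(rel - gg$truth$true_delays_s) <= 1 / 20000 + 1e-12))
  expect_equal(max(gg$truth$true_delays_s), 0.0057)

  # too-short duration cannot contain one train
  expect_error(generate_recording(
    synth_spec(fs_hz = 1000, duration_s = 2, seed = 1,
               stimulus = list(n_trials = 1, train_duration_s = 4,
                               pulse_rate_hz = 2, train_period_s = 6,
                               lead_s = 1))), "too short")
})

test_that("spike amplitudes are calibrated in MUA-band sd units", {
  spec <- synth_spec(fs_hz = 20000, duration_s = 20, seed = 3,
                     n_rows = 1, n_cols = 1, stimulus = NULL, evoked = NULL,
                     gamma_burst = NULL, oscillation = NULL,
                     common_source = NULL, line_noise = NULL,
                     spikes = list(rate_hz = 2, amp_sd = 6, kappa = 0))
  g <- generate_recording(spec)
  mua <- filter_mua(g$recording)
  # measured trough at injected spike times ~ -6 x background MUA sd
  at <- round(g$truth$spike_times_s[[1]] * 20000) + 1L
  at <- at[at > 40 & at < ncol(mua$data) - 40]
  troughs <- vapply(at, function(a) min(mua$data[1, (a - 20):(a + 20)]),
                    numeric(1))
  expect_lt(abs(median(troughs) / g$truth$sd_mua_uv[1] + 6), 0.8)
})

test_that("anesthesia epochs have the requested burst-suppression statistics", {
  spec <- synth_spec(fs_hz = 500, seed = 21,
                     anesthesia = list(duration_s = 60, suppression_fraction = 0.5))
  g <- generate_anesthesia_epoch(spec, "anesthetized")
  expect_identical(g$recording$state, "anesthetized")
  # fraction of 1-s windows classified quiet (RMS < 10% of burst RMS)
  r <- g$recording$data[1, ]
  rms <- sqrt(colMeans(matrix(r, 500)^2))
  quiet <- mean(rms < 0.1 * quantile(rms, 0.9))
  expect_lt(abs(quiet - 0.5), 0.1)
  # awake epoch has no suppression
  gw <- generate_anesthesia_epoch(spec, "awake")
  rw <- gw$recording$data[1, ]
  rmsw <- sqrt(colMeans(matrix(rw, 500)^2))
  expect_equal(mean(rmsw < 0.1 * quantile(rmsw, 0.9)), 0)
  # determinism
  expect_identical(generate_anesthesia_epoch(spec, "anesthetized")$recording$data,
                   g$recording$data)
})
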