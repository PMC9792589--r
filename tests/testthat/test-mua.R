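test_that("MUA power: zero in, closed-form tone value, linear scaling", {
  fs <- 20000
  t <- (0:(fs * 4 - 1)) / fs
  expect_equal(max(mua_power(signal_recording(numeric(fs), fs))$values), 0)
  # rectified 1 kHz tone of amplitude A low-passes to its mean 2A/pi
  A <- 12
  mp <- mua_power(signal_recording(A * sin(2 * pi * 1000 * t), fs))
  mid <- seq(fs, 3 * fs)
  expect_equal(mean(mp$values[1, mid]), 2 * A / pi, tolerance = 0.02)
  mp2 <- mua_power(signal_recording(2 * A * sin(2 * pi * 1000 * t), fs))
  expect_equal(mean(mp2$values[1, mid]), 4 * A / pi, tolerance = 0.02)
})

test_that("evoked MUA SNR matches its defining ratio", {
  fs <- 1000
  n <- 30 * fs
  vals <- matrix(1, 2, n)                 # baseline power 1
  onsets <- seq(5, 25, by = 2)
  for (on in onsets) {                    # response peak = 10 x baseline
    idx <- round(on * fs) + seq_len(round(0.1 * fs))
    vals[2, idx] <- 10
  }
  pt <- structure(list(values = vals, fs_hz = fs, channels = channel_grid(2, 1)),
                  class = "oe_mua_power")
  snr <- evoked_mua_snr(pt, onsets, response_window_s = c(0, 0.3))
  expect_equal(unname(snr[1]), 0, tolerance = 1e-10)        # peak = baseline
  expect_equal(unname(snr[2]), 10, tolerance = 1e-10)       # 10 dB
  pt$values[1, ] <- 0
  expect_error(evoked_mua_snr(pt, onsets), "zero baseline")
})

test_that("detection: crossing rate matches the Rice oracle; count monotone in k", {
  spec <- quiet_spec(fs_hz = 20000, duration_s = 50, seed = 14,
                     noise = list(white_sd_uv = 4, pink_sd_uv = 0, hash_sd_uv = 0))
  mua <- filter_mua(generate_recording(spec)$recording)
  counts <- vapply(c(3, 3.25, 3.5, 3.75, 4), function(k)
    length(detect_events(mua, k = k)[[1]]$event_times_s), integer(1))
  expect_true(all(diff(counts) <= 0))
  # Rice level-crossing oracle from the realized filter response:
  # nu0 = RMS frequency of the post-filtfilt noise spectrum (|H|^4 weighting)
  h <- signal::freqz(orgephys:::mua_filter(20000), n = 4096, Fs = 20000)
  w <- abs(h$h)^4
  nu0 <- sqrt(sum(h$f^2 * w) / sum(w))
  for (k in c(3, 3.5, 4)) {
    expected <- nu0 * exp(-k^2 / 2) * 50
    got <- length(detect_events(mua, k = k)[[1]]$event_times_s)
    expect_gt(got, 0.5 * expected)
    expect_lt(got, 1.5 * expected)
  }
  # flat channel: warning and an empty train
  flat <- signal_recording(numeric(20000), 20000)
  expect_warning(tr <- detect_events(flat), "flat")
  expect_length(tr[[1]]$event_times_s, 0)
})

test_that("event-triggered averages show locality and detect duplicated channels", {
  spec <- synth_spec(fs_hz = 20000, duration_s = 40, seed = 9,
                     n_rows = 2, n_cols = 2, stimulus = NULL, evoked = NULL,
                     gamma_burst = NULL, oscillation = NULL,
                     common_source = NULL, line_noise = NULL,
                     spikes = list(rate_hz = 12, amp_sd = 6, kappa = 0))
  rec <- generate_recording(spec)$recording
  rec$data <- rbind(rec$data, rec$data[1, ])  # channel 5 duplicates channel 1
  rec$channels <- channel_grid(5, 1)
  mua <- filter_mua(rec)
  trains <- detect_events(mua, k = 4)
  eta <- event_triggered_average(trains, mua, target_channel = 1)
  i0 <- which.min(abs(eta$lag_s))
  expect_lt(eta$mean[1, i0], -4 * eta$sd[1, i0] / sqrt(eta$n_events))
  # independent channels: mean waveform within the CLT envelope
  for (i in 2:4)
    expect_lt(max(abs(eta$mean[i, ])),
              3 * max(eta$sd[i, ]) / sqrt(eta$n_events) + 1e-12)
  # the duplicate shows the same lag-0 deflection (spread detection)
  expect_lt(eta$mean[5, i0], -4 * eta$sd[5, i0] / sqrt(eta$n_events))
  expect_error(event_triggered_average(trains, mua, target_channel = 99),
               "channel")
})

test_that("overlap counting is symmetric, translation-invariant, and calibrated", {
  a <- c(0.0015, 0.1, 0.5)
  expect_identical(overlap_count(a, a), 3L)
  expect_identical(overlap_count(a, c(0.2, 0.3)), 0L)
  b <- c(0.1004, 0.5001, 0.9)
  expect_identical(overlap_count(a, b), overlap_count(b, a))
  expect_identical(overlap_count(a + 2, b + 2), overlap_count(a, b))
  # independent Poisson trains: count near the binomial co-occupancy mean
  set.seed(15)
  reps <- vapply(1:40, function(r) {
    ta <- cumsum(rexp(1200, 2)); tb <- cumsum(rexp(1200, 2))
    overlap_count(ta[ta < 600], tb[tb < 600])
  }, integer(1))
  n_bins <- 600 / 0.001
  p <- (1200 / n_bins)
  expected <- n_bins * p * p
  expect_lt(abs(mean(reps) - expected), 4 * sd(reps) / sqrt(length(reps)))
})

test_that("shift test: maximal overlap for identical trains, empty-train guard", {
  tt <- seq(0.5, 119.5, length.out = 200)   # distinct 1-ms bins by construction
  r <- overlap_shift_test(tt, tt, duration_s = 120, n_shifts = 2000, seed = 2)
  expect_identical(r$observed, 200L)
  expect_lte(r$p_value, 2 / 2000)
  expect_warning(r0 <- overlap_shift_test(numeric(0), tt, duration_s = 120),
                 "empty")
  expect_identical(r0$p_value, 1)
  expect_error(overlap_shift_test(tt, tt, duration_s = 1.5), "too short")
})
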