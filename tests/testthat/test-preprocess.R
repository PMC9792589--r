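test_that("impedance exclusion flags channels and errors when nothing survives", {
  rec <- generate_recording(quiet_spec(
    fs_hz = 1000, duration_s = 1, n_rows = 2, n_cols = 2))$recording
  rec$channels$impedance_ohm <- rep(1.4e6, 4)   # the typical 1 kHz magnitude
  expect_true(all(exclude_channels(rec)$channels$included))
  rec$channels$impedance_ohm[3] <- 5e6
  out <- exclude_channels(rec)
  expect_identical(which(!out$channels$included), 3L)
  expect_error(exclude_channels(rec, max_impedance_ohm = 0), "all channels")
})

test_that("LFP low-pass is zero-phase with the specified band behaviour", {
  fs <- 20000
  t <- (0:(fs * 2 - 1)) / fs
  # passband tone: amplitude within 1%, phase shift < 1 degree
  rec <- signal_recording(sin(2 * pi * 10 * t), fs)
  y <- filter_lfp(rec)$data[1, ]
  mid <- seq(fs / 2, 3 * fs / 2)
  a <- 2 * mean(y[mid] * sin(2 * pi * 10 * t[mid]))
  b <- 2 * mean(y[mid] * cos(2 * pi * 10 * t[mid]))
  expect_lt(abs(sqrt(a^2 + b^2) - 1), 0.01)
  expect_lt(abs(atan2(b, a)) * 180 / pi, 1)
  # stopband tone attenuated >= 40 dB
  rec2 <- signal_recording(sin(2 * pi * 1000 * t), fs)
  y2 <- filter_lfp(rec2)$data[1, ]
  expect_lt(20 * log10(sd(y2[mid]) / sd(sin(2 * pi * 1000 * t[mid]))), -40)
  # impulse response symmetric about the impulse (zero-phase property)
  imp <- numeric(fs); imp[fs / 2] <- 1
  h <- filter_lfp(signal_recording(imp, fs))$data[1, ]
  k <- 300
  expect_equal(h[fs / 2 + 1:k], h[fs / 2 - 1:k], tolerance = 1e-6)
  expect_error(filter_lfp(signal_recording(rnorm(100), 400)), "too low")
})

test_that("MUA band-pass passes 1 kHz, rejects 10 Hz, and restricts energy", {
  fs <- 20000
  t <- (0:(fs * 2 - 1)) / fs
  mid <- seq(fs / 2, 3 * fs / 2)
  y <- filter_mua(signal_recording(sin(2 * pi * 1000 * t), fs))$data[1, ]
  expect_lt(abs(sd(y[mid]) / sd(sin(2 * pi * 1000 * t[mid])) - 1), 0.01)
  y2 <- filter_mua(signal_recording(sin(2 * pi * 10 * t), fs))$data[1, ]
  expect_lt(20 * log10(sd(y2[mid]) / sqrt(0.5)), -40)
  set.seed(1)
  w <- rnorm(fs)
  expect_lt(sd(filter_mua(signal_recording(w, fs))$data[1, ]), sd(w))
  expect_error(filter_mua(signal_recording(rnorm(100), 4000)), "MUA band")
  # zero-phase: cross-correlation of a passband tone peaks at lag 0
  x <- sin(2 * pi * 1500 * t)
  y3 <- filter_mua(signal_recording(x, fs))$data[1, ]
  cc <- ccf(y3[mid], x[mid], lag.max = 20, plot = FALSE)
  expect_equal(as.numeric(cc$lag[which.max(cc$acf)]), 0)
})

test_that("JADE leaves common-free data intact and removes a shared source", {
  set.seed(99)
  fs <- 250; n <- fs * 40
  # 8 identifiable local sources, no shared component: nothing removed,
  # reconstruction is exact
  local <- matrix(sign(rnorm(8 * n)) * rexp(8 * n) * 2, 8, n)
  rec <- recording(local, fs, channel_grid(2, 4))
  out <- remove_common_components(rec)
  expect_length(out$report$removed_component_indices, 0)
  expect_equal(out$recording$data, rec$data, tolerance = 1e-9)
  expect_equal(out$report$variance_removed_fraction, 0)

  # shared source with identical weights: a sparse train of transients
  # (motion-artifact-like, kurtotic at LFP timescales) - removed, locals kept
  common <- numeric(n)
  for (at in round(runif(30, 1, 39) * fs)) {
    nb <- round(0.08 * fs)
    common[at:(at + nb - 1)] <- common[at:(at + nb - 1)] +
      sample(c(-1, 1), 1) * rexp(1) * 0.5 * (1 - cos(2 * pi * seq_len(nb) / nb))
  }
  common <- 8 * common / sd(common)
  rec2 <- recording(local + rep(common, each = 8), fs, channel_grid(2, 4))
  out2 <- remove_common_components(rec2)
  expect_gte(length(out2$report$removed_component_indices), 1)
  resid <- out2$recording$data
  gain_in <- mean(apply(rec2$data, 1, function(v) cov(v, common))) / var(common)
  gain_out <- mean(apply(resid, 1, function(v) cov(v, common))) / var(common)
  expect_gte(1 - (gain_out / gain_in)^2, 0.9)
  for (i in 1:8) expect_gte(cor(resid[i, ], local[i, ]), 0.9)
  expect_error(remove_common_components(
    recording(matrix(1, 4, 100), fs, channel_grid(2, 2))), "rank")
})

test_that("uniformly added 60 Hz line noise is attenuated by >= 20 dB", {
  set.seed(7)
  fs <- 250; n <- fs * 60; t <- (0:(n - 1)) / fs
  local <- matrix(sign(rnorm(8 * n)) * rexp(8 * n) * 2, 8, n)
  line <- 8 * sin(2 * pi * 60 * t)
  rec <- recording(local + rep(line, each = 8), fs, channel_grid(2, 4))
  out <- remove_common_components(rec)
  p60 <- function(v) abs(sum(v * exp(-2i * pi * 60 * t)))^2
  drop_db <- 10 * log10(mean(vapply(1:8, function(i)
    p60(rec$data[i, ]) / p60(out$recording$data[i, ]), numeric(1))))
  expect_gte(drop_db, 20)
})

test_that("excluded channels never contribute to downstream statistics", {
  spec <- synth_spec(fs_hz = 2000, seed = 13, n_rows = 2, n_cols = 2,
                     stimulus = list(n_trials = 4, train_duration_s = 0.5,
                                     pulse_rate_hz = 2, train_period_s = 1.5,
                                     lead_s = 1),
                     spikes = NULL, gamma_burst = NULL, common_source = NULL,
                     line_noise = NULL)
  rec <- generate_recording(spec)$recording
  rec$channels$included[2] <- FALSE
  poisoned <- rec
  poisoned$data[2, ] <- 1e6 * sin(seq_len(ncol(rec$data)))   # garbage

  run <- function(r) {
    lfp <- filter_lfp(r)
    pm <- peak_map(trial_average(epoch_trials(lfp, pre_s = 0.1, post_s = 0.3)))
    bp <- band_power(morlet_spectrogram(decimate_recording(lfp, 500),
                                        freqs_hz = c(4, 8, 20)),
                     bands = data.frame(name = c("slow", "fast"),
                                        lo_hz = c(1, 10), hi_hz = c(10, 30)))
    list(pm = pm[-2, ], bp = bp[-2, ], excluded_peak = pm$peak_delay_s[2])
  }
  a <- run(rec); b <- run(poisoned)
  expect_equal(a$pm, b$pm)
  expect_equal(a$bp, b$bp)
  expect_true(is.na(b$excluded_peak))
})

test_that("decimation preserves passband content at the lower rate", {
  fs <- 20000
  t <- (0:(fs * 2 - 1)) / fs
  rec <- signal_recording(sin(2 * pi * 20 * t), fs)
  dec <- decimate_recording(rec, 500)
  expect_identical(dec$fs_hz, 500)
  expect_identical(ncol(dec$data), 1000L)
  mid <- 250:750
  td <- (mid - 1) / 500
  a <- 2 * mean(dec$data[1, mid] * sin(2 * pi * 20 * td))
  expect_lt(abs(a - 1), 0.02)
  expect_error(decimate_recording(rec, 333), "divide")
})
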