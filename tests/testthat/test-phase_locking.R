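test_that("DPSS tapers are orthonormal and bounded by the taper limit", {
  V <- dpss_tapers(512, time_bandwidth = 3, n_tapers = 5)
  expect_identical(dim(V), c(512L, 5L))
  expect_equal(crossprod(V), diag(5), tolerance = 1e-8)
  expect_gt(sum(V[, 1]), 0)
  expect_error(dpss_tapers(512, time_bandwidth = 3, n_tapers = 6), "2\\*NW")
})

test_that("multitaper phase is exact for tones and shifts analytically", {
  fs <- 625
  t <- (0:(fs * 20 - 1)) / fs
  rec <- signal_recording(cos(2 * pi * 5 * t), fs)
  pf <- multitaper_phase(rec, freqs_hz = 1:40)
  true_ph <- ((2 * pi * 5 * pf$t_centers_s + pi) %% (2 * pi)) - pi
  err <- Arg(exp(1i * (pf$phases[1, 5, ] - true_ph)))
  expect_lt(max(abs(err)), 0.05)
  # 50 ms delay shifts the 5 Hz phase by -2*pi*5*0.05 (mod 2*pi)
  rec2 <- signal_recording(cos(2 * pi * 5 * (t - 0.05)), fs)
  pf2 <- multitaper_phase(rec2, freqs_hz = 1:40)
  dph <- Arg(exp(1i * (pf2$phases[1, 5, ] - pf$phases[1, 5, ])))
  expect_equal(mean(dph), Arg(exp(-1i * 2 * pi * 5 * 0.05)), tolerance = 0.02)
  expect_error(multitaper_phase(rec, n_tapers = 9, time_bandwidth = 3), "2\\*NW")
  expect_error(multitaper_phase(rec, freqs_hz = c(5, 400)), "Nyquist")
})

test_that("white-noise phases are circularly uniform across windows", {
  set.seed(31)
  ok <- vapply(1:10, function(r) {
    rec <- signal_recording(rnorm(625 * 30), 625)
    pf <- multitaper_phase(rec, freqs_hz = c(5, 11), step_s = 1)
    rayleigh_test(pf$phases[1, 1, ])$p_value > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("PLV has its defining degenerate values and von Mises limit", {
  expect_equal(plv(rep(1.3, 10)), 1)
  expect_equal(plv(c(0, pi)), 0)
  expect_error(plv(numeric(0)), "phases")
  set.seed(32)
  expect_lt(abs(plv(rvonmises(1000, 0.7, 2)) - expected_plv(2)), 0.04)
  # global phase rotation leaves PLV unchanged
  ph <- rvonmises(300, 0, 1)
  expect_equal(plv(ph), plv(((ph + 2.1 + pi) %% (2 * pi)) - pi), tolerance = 1e-12)
})

test_that("bootstrap PLV: degenerate CI, small-sample floor, nested CIs", {
  pf <- fake_phase_field(rep(0.5, 400))
  ev <- pf$t_centers_s[1:100]
  b <- plv_bootstrap(ev, pf, 1, n_boot = 200, seed = 1)
  expect_equal(b$plv, 1)
  expect_equal(c(b$ci_lo, b$ci_hi), c(1, 1))
  # uniform phases: CI sits at the resultant's finite-sample floor
  set.seed(33)
  pf2 <- fake_phase_field(runif(400, -pi, pi))
  b2 <- plv_bootstrap(pf2$t_centers_s[1:80], pf2, 1, n_boot = 1000,
                      sample_size = 50, seed = 2)
  floor50 <- sqrt(pi / (4 * 50))
  expect_gt(b2$ci_hi, floor50)
  expect_lt(b2$ci_lo, floor50)
  expect_gt(b2$ci_lo, 0)
  # shrunken sample size is flagged
  b3 <- plv_bootstrap(pf2$t_centers_s[1:20], pf2, 1, n_boot = 100, seed = 3)
  expect_true(b3$shrunk)
  expect_identical(b3$sample_size, 20L)
  # 99% CI contains the 95% CI on the same resample stream
  q95 <- quantile(b2$boot[, 1], c(0.025, 0.975))
  q99 <- quantile(b2$boot[, 1], c(0.005, 0.995))
  expect_lte(q99[1], q95[1]); expect_gte(q99[2], q95[2])
})

test_that("PLV converges to the Bessel ratio with decreasing bias in n", {
  set.seed(34)
  bias <- vapply(c(50, 200, 1000, 5000), function(n)
    abs(mean(replicate(20, plv(rvonmises(n, 0, 2)))) - expected_plv(2)),
    numeric(1))
  expect_lt(bias[4], 0.01)
  expect_lt(bias[4], bias[1])
})

test_that("condition comparison flags constructed differences and not identity", {
  set.seed(35)
  pf_lock <- fake_phase_field(rbind(rvonmises(600, pi, 4),
                                    runif(600, -pi, pi)),
                              freqs_hz = c(5, 20))
  pf_unif <- fake_phase_field(rbind(runif(600, -pi, pi),
                                    runif(600, -pi, pi)),
                              freqs_hz = c(5, 20))
  ev <- pf_lock$t_centers_s[1:100]
  stim <- plv_bootstrap(ev, pf_lock, 1, n_boot = 600, seed = 4, condition = "stim")
  nos <- plv_bootstrap(ev, pf_unif, 1, n_boot = 600, seed = 5, condition = "no_stim")
  cmp <- plv_compare(stim, nos)
  expect_true(cmp$significant[cmp$freq_hz == 5])    # locked band flagged
  expect_false(cmp$significant[cmp$freq_hz == 20])  # unlocked band not flagged
  cmp0 <- plv_compare(stim, stim)
  expect_false(any(cmp0$significant))
  expect_true(all(plv_compare(stim, nos, method = "overlap")$significant ==
                    c(TRUE, FALSE)))
  bad <- nos; bad$freqs_hz <- c(4, 20)
  expect_error(plv_compare(stim, bad), "grids differ")
})

test_that("Rayleigh test: degenerate cases, exact-null monotonicity", {
  r <- rayleigh_test(rep(0.2, 60))
  expect_equal(r$Z, 60)
  expect_lt(r$p_value, 1e-20)
  r0 <- rayleigh_test(seq(0, 2 * pi, length.out = 61)[-61])  # uniform spacing
  expect_lt(r0$R, 1e-10)
  expect_gt(r0$p_value, 0.99)
  expect_warning(rsmall <- rayleigh_test(c(0, 1, 2)), "n = 3")
  expect_identical(rsmall$p_value, 1)
  # p monotone decreasing in R at fixed n
  ps <- vapply(c(0.1, 0.2, 0.3, 0.4), function(R)
    exp(sqrt(1 + 4 * 67 + 4 * (67^2 - (67 * R)^2)) - (1 + 2 * 67)), numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("spatial PLV map peaks where the locking oscillation lives", {
  # 2 x 2 grid: only channel 4 (reference corner) carries the 5 Hz rhythm
  spec <- synth_spec(fs_hz = 1250, duration_s = 150, seed = 36,
                     n_rows = 2, n_cols = 2, stimulus = NULL, evoked = NULL,
                     gamma_burst = NULL, common_source = NULL, line_noise = NULL,
                     noise = list(white_sd_uv = 3, pink_sd_uv = 3, hash_sd_uv = 0),
                     oscillation = list(freq_hz = 5, amp_uv = c(0, 0, 0, 40)),
                     spikes = list(rate_hz = 4, amp_sd = 0, amp_uv = 0,
                                   kappa = 4, lock_freq_hz = 5, mu = pi,
                                   stim_gated = FALSE))
  g <- generate_recording(spec)
  pf <- multitaper_phase(decimate_recording(filter_lfp(g$recording), 625),
                         freqs_hz = 1:10)
  ev <- g$truth$spike_times_s[[4]]
  m <- plv_spatial_map(ev, pf, band = c(4, 6), n_boot = 300, seed = 6)
  expect_identical(which.max(m$plv), 4L)
  expect_gt(m$plv[4], 0.6)
  # partition splits events by the pulse windows
  stim <- stimulus_protocol(c(1, 3, 5), 0.1, 2, 0.5, 3)
  pe <- partition_events(c(0.5, 1.05, 1.3, 3.15, 4.9), stim, post_pad_s = 0.1)
  expect_equal(pe$stim, c(1.05, 3.15))
  expect_equal(pe$no_stim, c(0.5, 1.3, 4.9))
})
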