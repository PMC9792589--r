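# Morlet-wavelet time-frequency analysis, band-power summaries, and the
# organoid/cortex band-power ratio with its across-channel t test.
#
# Wavelets are analytic complex Morlets with a fixed number of cycles
# (default 7), normalized to unit discrete L2 energy so that the squared
# magnitude is a power density: stationary white noise yields the same
# expected value at every analysis frequency ("per-Hz" units up to one global
# constant), making band densities directly comparable.

# Complex Morlet transform of one signal; returns an n_freq x n_time complex
# matrix. Frequency-domain implementation; the signal is zero-padded by the
# slowest wavelet's half-length so wrap-around cannot reach the data.
morlet_transform <- function(x, fs, freqs_hz, n_cycles = 7) {
  if (max(freqs_hz) >= fs / 2) stopf("frequency grid exceeds Nyquist (%g Hz)", fs / 2)
  if (min(freqs_hz) <= 0) stopf("frequencies must be > 0")
  n <- length(x)
  sigma_t_max <- n_cycles / (2 * pi * min(freqs_hz))
  pad <- ceiling(4 * sigma_t_max * fs)
  n_fft <- next_pow2(n + 2 * pad)
  X <- stats::fft(c(x, numeric(n_fft - n)))
  f_axis <- (seq_len(n_fft) - 1) / n_fft * fs
  out <- matrix(0i, length(freqs_hz), n)
  for (k in seq_along(freqs_hz)) {
    f0 <- freqs_hz[k]
    sigma_f <- f0 / n_cycles
    H <- numeric(n_fft)
    pos <- f_axis <= fs / 2            # analytic: positive frequencies only
    H[pos] <- exp(-(f_axis[pos] - f0)^2 / (2 * sigma_f^2))
    # unit discrete L2 energy: sum |w[n]|^2 = (1/N) sum |H_k|^2 = 1
    H <- H * sqrt(n_fft / sum(H^2))
    y <- stats::fft(X * H, inverse = TRUE) / n_fft
    out[k, ] <- y[seq_len(n)]
  }
  out
}

#' Morlet wavelet spectrogram
#'
#' Squared magnitude of the analytic Morlet transform for every included
#' channel at each frequency of the grid. Power is quadratic in the input
#' (scaling the signal by a scales power by a^2) and expressed in density
#' units: white noise has flat expected power across frequencies. Excluded
#' channels yield `NA`.
#'
#' @param rec an [recording()].
#' @param freqs_hz analysis frequencies, strictly increasing, below Nyquist;
#'   default: 60-point logarithmic grid over 1-150 Hz.
#' @param n_cycles wavelet width in cycles (default 7).
#' @return object of class `oe_tfa`: `values` (channel x frequency x time
#'   power array), `freqs_hz`, `t_axis_s`, `fs_hz`, `method = "morlet"`,
#'   `params`, `channels`.
#' @export
morlet_spectrogram <- function(rec, freqs_hz = NULL, n_cycles = 7) {
  freqs_hz <- freqs_hz %||% exp(seq(log(1), log(150), length.out = 60))
  if (any(diff(freqs_hz) <= 0)) stopf("freqs_hz must be strictly increasing")
  n_ch <- nrow(rec$data)
  n <- ncol(rec$data)
  vals <- array(NA_real_, c(n_ch, length(freqs_hz), n))
  for (i in included_idx(rec)) {
    w <- morlet_transform(rec$data[i, ], rec$fs_hz, freqs_hz, n_cycles)
    vals[i, , ] <- abs(w)^2
  }
  structure(list(values = vals, freqs_hz = freqs_hz,
                 t_axis_s = (seq_len(n) - 1) / rec$fs_hz,
                 fs_hz = rec$fs_hz, method = "morlet",
                 params = list(n_cycles = n_cycles),
                 channels = rec$channels),
            class = "oe_tfa")
}

#' Trial-averaged Morlet spectrogram
#'
#' Per-trial Morlet power around each stimulus, averaged over trials
#' (average of single-trial power, so non-phase-locked responses are
#' retained).
#'
#' @param tt an `oe_trials` from [epoch_trials()].
#' @param freqs_hz analysis frequencies (default: logarithmic 1-150 Hz grid,
#'   trimmed to what the epoch length supports).
#' @param n_cycles wavelet width in cycles (default 7).
#' @return an `oe_tfa` with `t_axis_s` relative to pulse onset.
#' @export
trial_averaged_spectrogram <- function(tt, freqs_hz = NULL, n_cycles = 7) {
  if (!inherits(tt, "oe_trials")) stopf("tt must be an oe_trials")
  freqs_hz <- freqs_hz %||% exp(seq(log(1), log(150), length.out = 60))
  n_tr <- dim(tt$values)[1]
  n_ch <- dim(tt$values)[2]
  n_t <- dim(tt$values)[3]
  inc <- which(tt$channels$included)
  vals <- array(0, c(n_ch, length(freqs_hz), n_t))
  vals[setdiff(seq_len(n_ch), inc), , ] <- NA_real_
  for (tr in seq_len(n_tr)) {
    for (i in inc) {
      w <- morlet_transform(tt$values[tr, i, ], tt$fs_hz, freqs_hz, n_cycles)
      vals[i, , ] <- vals[i, , ] + abs(w)^2 / n_tr
    }
  }
  structure(list(values = vals, freqs_hz = freqs_hz, t_axis_s = tt$t_axis_s,
                 fs_hz = tt$fs_hz, method = "morlet",
                 params = list(n_cycles = n_cycles, n_trials = n_tr),
                 channels = tt$channels),
            class = "oe_tfa")
}

#' Default frequency-band definitions
#'
#' Delta 1-4, theta 4-8, alpha 8-12, beta 12-30, low gamma 30-60, high gamma
#' 60-150 Hz. Band edges are conventions (phase-locking analyses use a 4-6 Hz
#' theta window); all are configurable.
#'
#' @return data.frame with columns `name`, `lo_hz`, `hi_hz`.
#' @export
default_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "low_gamma", "high_gamma"),
             lo_hz = c(1, 4, 8, 12, 30, 60),
             hi_hz = c(4, 8, 12, 30, 60, 150),
             stringsAsFactors = FALSE)
}

#' Band power per channel
#'
#' Mean power density over time and over the frequency bins inside each band
#' (half-open `[lo, hi)`).
#'
#' @param tfa an `oe_tfa`.
#' @param bands data.frame as from [default_bands()].
#' @return matrix channel x band of mean power density; `NA` for excluded
#'   channels.
#' @export
band_power <- function(tfa, bands = default_bands()) {
  if (!inherits(tfa, "oe_tfa")) stopf("tfa must be an oe_tfa")
  n_ch <- dim(tfa$values)[1]
  out <- matrix(NA_real_, n_ch, nrow(bands),
                dimnames = list(tfa$channels$channel_id, bands$name))
  for (b in seq_len(nrow(bands))) {
    sel <- tfa$freqs_hz >= bands$lo_hz[b] & tfa$freqs_hz < bands$hi_hz[b]
    if (!any(sel)) stopf("band '%s' contains no grid frequencies", bands$name[b])
    for (i in seq_len(n_ch)) {
      v <- tfa$values[i, sel, , drop = FALSE]
      out[i, b] <- mean(v)
    }
  }
  out
}

#' Organoid/cortex band-power ratio with per-band t test
#'
#' Per band: mean power of organoid-labeled channels divided by mean power of
#' cortex-labeled channels (cortex normalized to 1), with a two-sample t test
#' across channels (default one-sided, organoid < cortex). Excluded channels
#' and `NA` rows are dropped; each region needs at least 2 channels.
#'
#' @param bp channel x band power matrix from [band_power()].
#' @param channels the channel metadata table of the recording.
#' @param alternative t-test sidedness (default `"less"`).
#' @return data.frame with `band`, `organoid_ratio`, `cortex_ratio` (= 1),
#'   `p_value`, `n_organoid`, `n_cortex`.
#' @export
region_power_ratio <- function(bp, channels,
                               alternative = c("less", "two.sided", "greater")) {
  alternative <- match.arg(alternative)
  usable <- channels$included & !is.na(bp[, 1])
  org <- usable & channels$region == "organoid"
  ctx <- usable & channels$region == "cortex"
  if (sum(org) < 2 || sum(ctx) < 2)
    stopf("need >= 2 usable channels per region (organoid %d, cortex %d)",
          sum(org), sum(ctx))
  out <- data.frame(band = colnames(bp),
                    organoid_ratio = NA_real_, cortex_ratio = 1,
                    p_value = NA_real_,
                    n_organoid = sum(org), n_cortex = sum(ctx),
                    stringsAsFactors = FALSE)
  for (b in seq_len(ncol(bp))) {
    po <- bp[org, b]; pc <- bp[ctx, b]
    out$organoid_ratio[b] <- mean(po) / mean(pc)
    out$p_value[b] <- stats::t.test(po, pc, alternative = alternative)$p.value
  }
  out
}
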