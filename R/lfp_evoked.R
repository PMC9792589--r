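# Stimulus-evoked LFP analysis: trial epoching, trial averages, per-channel
# peak amplitude/latency maps, and the shuffle-based test for a propagation
# delay between a channel pair.

# Group the flat pulse-onset list into trains: a new train starts wherever
# the gap exceeds 1.5 pulse periods. Returns a list of onset vectors.
pulse_trains <- function(stim) {
  on <- stim$onsets_s
  if (!length(on)) return(list())
  brk <- c(0, which(diff(on) > 1.5 / stim$pulse_rate_hz), length(on))
  lapply(seq_len(length(brk) - 1), function(k) on[(brk[k] + 1):brk[k + 1]])
}

#' Epoch a recording into stimulus-locked trials
#'
#' Extracts one epoch per stimulus train, aligned to the onset of the
#' `which_pulse`-th pulse of each train, spanning `[-pre_s, post_s)` around
#' that onset. Trials whose window falls outside the recording are dropped
#' with a warning.
#'
#' @param rec an LFP-filtered [recording()] with a stimulus protocol.
#' @param which_pulse 1-based pulse index within each train (default 1).
#' @param pre_s,post_s window before/after the pulse onset (s).
#' @return object of class `oe_trials`: `values` (trial x channel x time
#'   array, uV), `t_axis_s` (time relative to onset), `baseline_window_s`
#'   (`c(-pre_s, 0)`), `n_trials`, `fs_hz`, `channels`, `onsets_s` (the onset
#'   of the selected pulse for each kept trial).
#' @export
epoch_trials <- function(rec, which_pulse = 1, pre_s = 0.2, post_s = 0.5) {
  if (is.null(rec$stimulus)) stopf("recording has no stimulus protocol")
  trains <- pulse_trains(rec$stimulus)
  if (!length(trains)) stopf("stimulus protocol has no pulses")
  onsets <- vapply(trains, function(tr) {
    if (which_pulse > length(tr)) NA_real_ else tr[which_pulse]
  }, numeric(1))
  onsets <- onsets[!is.na(onsets)]
  fs <- rec$fs_hz
  n <- ncol(rec$data)
  n_pre <- round(pre_s * fs)
  n_post <- round(post_s * fs)
  n_t <- n_pre + n_post
  # half-open [onset - pre, onset + post): first sample at index - n_pre
  i_on <- round(onsets * fs) + 1L
  ok <- (i_on - n_pre) >= 1L & (i_on + n_post - 1L) <= n
  if (any(!ok))
    warnf("%d trial(s) exceed record bounds and were dropped", sum(!ok))
  if (!any(ok)) stopf("zero usable trials")
  i_on <- i_on[ok]
  n_ch <- nrow(rec$data)
  vals <- array(NA_real_, c(length(i_on), n_ch, n_t))
  for (tr in seq_along(i_on)) {
    idx <- (i_on[tr] - n_pre):(i_on[tr] + n_post - 1L)
    vals[tr, , ] <- rec$data[, idx]
  }
  structure(list(values = vals,
                 t_axis_s = (seq_len(n_t) - n_pre - 1) / fs,
                 baseline_window_s = c(-pre_s, 0),
                 n_trials = length(i_on),
                 fs_hz = fs,
                 channels = rec$channels,
                 onsets_s = onsets[ok]),
            class = "oe_trials")
}

#' Trial-averaged evoked response
#'
#' Pointwise mean and sample standard deviation over trials, per channel.
#'
#' @param tt an `oe_trials` from [epoch_trials()].
#' @return object of class `oe_trial_average`: `mean` and `sd` (channel x
#'   time matrices), `t_axis_s`, `baseline_window_s`, `n_trials`, `channels`.
#' @export
trial_average <- function(tt) {
  if (!inherits(tt, "oe_trials")) stopf("tt must be an oe_trials")
  n_tr <- dim(tt$values)[1]
  mu <- apply(tt$values, c(2, 3), mean)
  sdv <- if (n_tr > 1) apply(tt$values, c(2, 3), stats::sd)
         else matrix(0, dim(tt$values)[2], dim(tt$values)[3])
  structure(list(mean = mu, sd = sdv, t_axis_s = tt$t_axis_s,
                 baseline_window_s = tt$baseline_window_s,
                 n_trials = n_tr, channels = tt$channels),
            class = "oe_trial_average")
}

#' Per-channel peak amplitude and delay map
#'
#' For each included channel, finds the extremum of the chosen polarity in
#' the trial-averaged trace inside the search window. Amplitude is reported
#' relative to the pre-onset baseline mean; delay is relative to pulse onset.
#' Flat traces (no extremum) and excluded channels yield `NA`.
#'
#' @param ta an `oe_trial_average` from [trial_average()].
#' @param search_window_s window (s, relative to onset) searched for the
#'   peak; default `c(0.01, 0.08)`, bracketing typical evoked latencies while
#'   excluding the stimulus artifact.
#' @param polarity `"negative"` (default; the evoked LFP's first deflection),
#'   `"positive"`, or `"absolute"`.
#' @return object of class `oe_peak_map`: data.frame with `channel_id`,
#'   `row`, `col`, `region`, `included`, `peak_amp_uv`, `peak_delay_s`; the
#'   window and polarity as attributes.
#' @export
peak_map <- function(ta, search_window_s = c(0.01, 0.08),
                     polarity = c("negative", "positive", "absolute")) {
  polarity <- match.arg(polarity)
  if (!inherits(ta, "oe_trial_average")) stopf("ta must be an oe_trial_average")
  t_axis <- ta$t_axis_s
  win <- t_axis >= search_window_s[1] & t_axis < search_window_s[2]
  if (!any(win)) stopf("search window outside the epoch")
  base <- t_axis >= ta$baseline_window_s[1] & t_axis < ta$baseline_window_s[2]
  ch <- ta$channels
  amp <- delay <- rep(NA_real_, nrow(ch))
  for (i in which(ch$included)) {
    tr <- ta$mean[i, ]
    b <- if (any(base)) mean(tr[base]) else 0
    seg <- tr[win]
    if (max(seg) - min(seg) < .Machine$double.eps^0.5) next  # flat: no peak
    j <- switch(polarity,
                negative = which.min(seg),
                positive = which.max(seg),
                absolute = which.max(abs(seg - b)))
    amp[i] <- seg[j] - b
    delay[i] <- t_axis[win][j]
  }
  out <- data.frame(channel_id = ch$channel_id, row = ch$row, col = ch$col,
                    region = ch$region, included = ch$included,
                    peak_amp_uv = amp, peak_delay_s = delay,
                    stringsAsFactors = FALSE)
  structure(out, class = c("oe_peak_map", "data.frame"),
            search_window_s = search_window_s, polarity = polarity)
}

#' Shuffle test for the delay between two channels
#'
#' The observed statistic is `delta = delay_b - delay_a` from the peak map.
#' The null is built by permuting the per-channel delay values across
#' channels `n_shuffles` times (without replacement) and recomputing the
#' pair's delta; the p-value comes from a t statistic of the observed delta
#' against the null sample's mean and standard deviation with
#' `n_shuffles - 1` degrees of freedom.
#'
#' @param pm an `oe_peak_map`.
#' @param chan_a,chan_b channel ids of the pair (delta = b minus a).
#' @param n_shuffles number of permutations (default 1000).
#' @param seed optional RNG seed.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`; the
#'   one-sided options test whether channel b lags (leads) channel a.
#' @return list: `observed_delta_s`, `null_mean`, `null_sd`, `t`, `p_value`,
#'   `n_shuffles`, `alternative`.
#' @export
delay_shuffle_test <- function(pm, chan_a, chan_b, n_shuffles = 1000,
                               seed = NULL,
                               alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  delays <- pm$peak_delay_s[pm$included]
  delays <- delays[!is.na(delays)]
  if (length(delays) < 3) stopf("fewer than 3 valid channel delays")
  da <- pm$peak_delay_s[match(chan_a, pm$channel_id)]
  db <- pm$peak_delay_s[match(chan_b, pm$channel_id)]
  if (is.na(da) || is.na(db)) stopf("channel %s or %s absent from the peak map",
                                    chan_a, chan_b)
  if (!is.null(seed)) set.seed(seed)
  m <- length(delays)
  null <- vapply(seq_len(n_shuffles), function(k) {
    p <- sample.int(m)
    delays[p[2]] - delays[p[1]]
  }, numeric(1))
  observed <- db - da
  mu <- mean(null)
  sdv <- stats::sd(null)
  tstat <- if (sdv > .Machine$double.eps^0.5) (observed - mu) / sdv
           else if (abs(observed - mu) < .Machine$double.eps^0.5) 0
           else sign(observed - mu) * Inf
  df <- n_shuffles - 1
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(tstat), df),
              greater = stats::pt(tstat, df, lower.tail = FALSE),
              less = stats::pt(tstat, df))
  list(observed_delta_s = observed, null_mean = mu, null_sd = sdv,
       t = tstat, p_value = min(1, p), n_shuffles = n_shuffles,
       alternative = alternative)
}
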