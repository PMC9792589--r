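# Preprocessing: impedance-based channel exclusion, removal of shared
# (volume-conducted) components by blind source separation, and zero-phase
# Chebyshev band extraction of LFP (< 250 Hz) and MUA (0.5-3 kHz).
#
# All filters are Chebyshev type II with 40 dB stopband attenuation, applied
# forward-backward (zero phase); the stated order is the design order before
# the forward-backward pass.

lfp_filter <- function(fs, cutoff_hz = 250, order = 8) {
  if (fs <= 2 * cutoff_hz) stopf("fs = %g Hz too low for a %g Hz low-pass", fs, cutoff_hz)
  # stopband edge at 1.2 x cutoff: >= 40 dB there and above (80 dB after filtfilt)
  signal::cheby2(order, 40, 1.2 * cutoff_hz / (fs / 2), type = "low")
}

mua_filter <- function(fs, band = c(500, 3000), order = 6) {
  if (fs < 8000) stopf("fs = %g Hz cannot represent the 0.5-3 kHz MUA band", fs)
  # stopband edges at 250 Hz and 6 kHz (>= 40 dB after the forward-backward pass)
  signal::cheby2(order / 2, 40, c(band[1] / 2, 2 * band[2]) / (fs / 2), type = "pass")
}

apply_filtfilt <- function(rec, flt) {
  for (i in seq_len(nrow(rec$data)))
    rec$data[i, ] <- signal::filtfilt(flt, rec$data[i, ])
  rec
}

#' Exclude high-impedance channels
#'
#' Channels with 1 kHz impedance magnitude above the threshold are flagged
#' `included = FALSE`. Data are retained but every downstream statistic skips
#' excluded channels.
#'
#' @param rec an [recording()].
#' @param max_impedance_ohm exclusion threshold in ohms (default 4e6).
#' @return the recording with updated inclusion flags.
#' @export
exclude_channels <- function(rec, max_impedance_ohm = 4e6) {
  bad <- rec$channels$impedance_ohm > max_impedance_ohm
  rec$channels$included <- rec$channels$included & !bad
  if (!any(rec$channels$included))
    stopf("all channels excluded at impedance threshold %g Ohm", max_impedance_ohm)
  log_step(rec, "exclude_channels: %d/%d excluded (> %g Ohm)",
           sum(!rec$channels$included), nrow(rec$channels), max_impedance_ohm)
}

#' Extract the LFP band (zero-phase low-pass below 250 Hz)
#'
#' 8th-order Chebyshev type II low-pass (40 dB stopband starting at 1.2 x
#' cutoff) applied forward-backward: zero phase shift, passband amplitude
#' preserved within 1%.
#'
#' @param rec an [recording()].
#' @param cutoff_hz passband edge (default 250).
#' @param order design order (default 8).
#' @return the filtered recording.
#' @export
filter_lfp <- function(rec, cutoff_hz = 250, order = 8) {
  rec <- apply_filtfilt(rec, lfp_filter(rec$fs_hz, cutoff_hz, order))
  log_step(rec, "filter_lfp: zero-phase Chebyshev II low-pass %g Hz (order %d)",
           cutoff_hz, order)
}

#' Extract the MUA band (zero-phase band-pass 0.5-3 kHz)
#'
#' 6th-order Chebyshev type II band-pass with stopband edges at 250 Hz and
#' 6 kHz (>= 40 dB there after the forward-backward pass).
#'
#' @param rec an [recording()].
#' @param band passband edges in Hz (default `c(500, 3000)`).
#' @param order design order (default 6).
#' @return the filtered recording.
#' @export
filter_mua <- function(rec, band = c(500, 3000), order = 6) {
  rec <- apply_filtfilt(rec, mua_filter(rec$fs_hz, band, order))
  log_step(rec, "filter_mua: zero-phase Chebyshev II band-pass %g-%g Hz (order %d)",
           band[1], band[2], order)
}

#' Decimate a recording to a lower sampling rate
#'
#' Zero-phase anti-alias low-pass (Chebyshev II, stopband at the new Nyquist)
#' followed by subsampling. The target rate must divide the original rate.
#'
#' @param rec an [recording()].
#' @param target_fs_hz new sampling rate.
#' @return the decimated recording.
#' @export
decimate_recording <- function(rec, target_fs_hz) {
  q <- rec$fs_hz / target_fs_hz
  if (abs(q - round(q)) > 1e-9) stopf("target_fs_hz must divide fs (%g)", rec$fs_hz)
  q <- round(q)
  if (q == 1) return(rec)
  flt <- signal::cheby2(8, 40, (target_fs_hz / 2) / (rec$fs_hz / 2), type = "low")
  keep <- seq(1, ncol(rec$data), by = q)
  newdata <- matrix(0, nrow(rec$data), length(keep))
  for (i in seq_len(nrow(rec$data)))
    newdata[i, ] <- signal::filtfilt(flt, rec$data[i, ])[keep]
  rec$data <- newdata
  rec$fs_hz <- target_fs_hz
  log_step(rec, "decimate: %g Hz (factor %d)", target_fs_hz, q)
}

# ---------------------------------------------------------------------------
# JADE: joint approximate diagonalization of fourth-order cumulant matrices
# (Cardoso & Souloumiac). Deterministic - no random initialization.
# Returns unmixing B (components x channels) and mixing A = solve(B).
# ---------------------------------------------------------------------------
jade_decompose <- function(X, eps = NULL, max_sweeps = 100) {
  n_ch <- nrow(X)
  n <- ncol(X)
  if (n_ch < 2) stopf("ICA needs at least 2 channels")
  X <- X - rowMeans(X)

  # whitening
  C <- tcrossprod(X) / n
  eg <- eigen(C, symmetric = TRUE)
  if (max(eg$values) <= 0 || min(eg$values) < 1e-12 * max(eg$values))
    stopf("ICA failed: rank-deficient data (smallest eigenvalue ~ 0)")
  W <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)   # whitener
  iW <- eg$vectors %*% diag(sqrt(eg$values))         # its inverse
  Z <- W %*% X

  # cumulant matrix set: Q(M) = E[(z' M z) z z'] - M - M' - tr(M) I
  m <- n_ch
  n_cm <- m * (m + 1) / 2
  CM <- vector("list", n_cm)
  k <- 1L
  for (i in seq_len(m)) {
    for (j in seq_len(i)) {
      w <- Z[i, ] * Z[j, ]
      Q <- (Z * rep(w, each = m)) %*% t(Z) / n
      if (i == j) {
        Q <- Q - diag(m) - 2 * tcrossprod(diag(m)[, i])
      } else {
        Q <- Q - tcrossprod(diag(m)[, i], diag(m)[, j]) -
          tcrossprod(diag(m)[, j], diag(m)[, i])
        Q <- Q * sqrt(2)
      }
      CM[[k]] <- Q
      k <- k + 1L
    }
  }

  # joint diagonalization by Jacobi rotations
  eps <- eps %||% max(1e-7, 1 / sqrt(n) / 100)
  V <- diag(m)
  for (sweep in seq_len(max_sweeps)) {
    rotated <- FALSE
    for (p in seq_len(m - 1)) {
      for (q in (p + 1):m) {
        g1 <- vapply(CM, function(Q) Q[p, p] - Q[q, q], numeric(1))
        g2 <- vapply(CM, function(Q) Q[p, q] + Q[q, p], numeric(1))
        ton <- sum(g1^2) - sum(g2^2)
        toff <- 2 * sum(g1 * g2)
        theta <- 0.5 * atan2(toff, ton + sqrt(ton^2 + toff^2))
        if (abs(theta) > eps) {
          rotated <- TRUE
          cs <- cos(theta); sn <- sin(theta)
          G <- matrix(c(cs, sn, -sn, cs), 2, 2)   # [c -s; s c]
          pq <- c(p, q)
          for (k in seq_along(CM)) {
            Q <- CM[[k]]
            Q[pq, ] <- t(G) %*% Q[pq, ]
            Q[, pq] <- Q[, pq] %*% G
            CM[[k]] <- Q
          }
          V[, pq] <- V[, pq] %*% G
        }
      }
    }
    if (!rotated) break
  }
  if (rotated && sweep == max_sweeps)
    warnf("joint diagonalization did not fully converge after %d sweeps", max_sweeps)

  B <- t(V) %*% W           # components x channels unmixing
  A <- iW %*% V             # channels x components mixing
  list(B = B, A = A)
}

#' Remove components shared across channels (volume conduction, line noise)
#'
#' Decomposes the included channels into independent components with the JADE
#' algorithm (fourth-order blind source separation, deterministic), estimated
#' on data decimated to `est_fs_hz` so the estimate is driven by the LFP-band
#' structure; removal is applied to the broadband signal through the
#' estimated mixing, keeping the MUA band intact. A component is classified
#' as shared when the coefficient of variation of its absolute mixing weights
#' across channels is at most `uniformity_cv_max` (a perfectly
#' volume-conducted source has identical weight everywhere, CV = 0);
#' `components` overrides the automatic rule with explicit indices. Removed
#' components are zeroed and the signal reconstructed from the rest.
#'
#' @param rec an [recording()] with at least 4 included channels.
#' @param uniformity_cv_max CV threshold for automatic removal (default 0.25).
#' @param max_components at most this many components (the most uniform
#'   candidates) are removed automatically (default 3: physically, only a
#'   few shared sources exist - volume conduction, mains noise, motion).
#' @param est_fs_hz sampling rate for ICA estimation (default 250 Hz).
#' @param components optional explicit component indices to remove.
#' @param exclude_windows_s optional 2-column matrix of `[start, end)` time
#'   windows (s) dropped from the estimation data (removal is still applied
#'   to the full recording). Use this to estimate the shared subspace on
#'   inter-trial segments so strong stimulus-evoked responses - which are
#'   correlated across channels but not volume-conducted - cannot leak into
#'   the removed components; the shared sources are stationary, so they are
#'   identified from the spontaneous segments. With a stimulus protocol
#'   present, [run_pipeline()] excludes a window after every pulse.
#' @param seed unused (JADE is deterministic); kept so callers can treat all
#'   stochastic stages uniformly.
#' @return list: `recording` (cleaned), `report` (an `ICAReport`: number of
#'   components, removed indices, per-component mixing-uniformity CV,
#'   fraction of variance removed).
#' @export
remove_common_components <- function(rec, uniformity_cv_max = 0.25,
                                     max_components = 3,
                                     est_fs_hz = 250, components = NULL,
                                     exclude_windows_s = NULL, seed = NULL) {
  inc <- included_idx(rec)
  if (length(inc) < 4) stopf("need >= 4 included channels for ICA")
  X <- rec$data[inc, , drop = FALSE]
  if (!all(is.finite(X))) stopf("non-finite data; cannot run ICA")

  q <- max(1, floor(rec$fs_hz / est_fs_hz))
  Xest <- if (q > 1) {
    flt <- signal::cheby2(8, 40, (rec$fs_hz / q / 2) / (rec$fs_hz / 2), "low")
    t(apply(X, 1, function(v) signal::filtfilt(flt, v)[seq(1, length(v), by = q)]))
  } else X
  if (!is.null(exclude_windows_s)) {
    w <- matrix(exclude_windows_s, ncol = 2)
    t_est <- (seq(1, ncol(X), by = q) - 1) / rec$fs_hz
    drop <- rep(FALSE, length(t_est))
    for (k in seq_len(nrow(w)))
      drop <- drop | (t_est >= w[k, 1] & t_est < w[k, 2])
    if (sum(!drop) < 10 * nrow(X))
      stopf("exclude_windows_s leaves too few samples for ICA estimation")
    Xest <- Xest[, !drop, drop = FALSE]
  }

  dec <- jade_decompose(Xest)
  mix_cv <- apply(abs(dec$A), 2, function(w) stats::sd(w) / mean(w))
  # volume conduction is same-polarity everywhere: require sign-consistent
  # weights in addition to near-uniform magnitude; and only a handful of
  # shared sources exist physically (volume conduction, line noise, motion),
  # so at most `max_components` candidates - the most uniform ones - are
  # removed (projecting out many same-sign directions would eat into any
  # spatially smooth local signal, e.g. an evoked response gradient)
  remove <- if (is.null(components)) {
    same_sign <- apply(dec$A, 2, function(w) all(w > 0) || all(w < 0))
    cand <- which(mix_cv <= uniformity_cv_max & same_sign)
    cand[order(mix_cv[cand])][seq_len(min(length(cand), max_components))]
  } else as.integer(components)
  if (length(remove) >= nrow(X))
    stopf("ICA would remove all %d components", nrow(X))

  mu <- rowMeans(X)
  if (length(remove)) {
    S <- dec$B %*% (X - mu)                    # broadband source estimates
    keep <- setdiff(seq_len(nrow(X)), remove)
    Xc <- dec$A[, keep, drop = FALSE] %*% S[keep, , drop = FALSE] + mu
  } else {
    Xc <- X
  }
  var_in <- sum(apply(X, 1, stats::var))
  var_removed <- max(0, min(1, 1 - sum(apply(Xc, 1, stats::var)) / var_in))

  rec$data[inc, ] <- Xc
  rec <- log_step(rec,
    "remove_common_components: JADE on %d channels @ %g Hz, removed %s (cv <= %g)",
    length(inc), rec$fs_hz / q,
    if (length(remove)) paste(remove, collapse = ",") else "none",
    uniformity_cv_max)
  report <- list(n_components = nrow(X),
                 removed_component_indices = as.integer(remove),
                 mixing_uniformity = mix_cv,
                 variance_removed_fraction = var_removed)
  list(recording = rec, report = report)
}
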