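# Recording bundle data model and on-disk formats.
#
# Units are fixed package-wide: voltages in microvolts, times in seconds,
# sample indices 0-based with sample 0 at t = 0, epoch windows half-open
# [start, end). Conversions happen only at I/O boundaries.

REGION_LEVELS <- c("organoid", "cortex", "ambiguous")

#' Channel metadata table for a rectangular microelectrode grid
#'
#' Builds the per-channel metadata table for an `n_rows` x `n_cols` grid with
#' the given pitch. Channels are numbered row-major starting at 1; positions
#' are `x_um = col * pitch_um`, `y_um = row * pitch_um` with 0-based row/col
#' indices.
#'
#' @param n_rows,n_cols grid dimensions (default 4 x 4).
#' @param pitch_um electrode pitch in micrometres (default 500).
#' @param region character vector (recycled) of region labels, one of
#'   `"organoid"`, `"cortex"`, `"ambiguous"`. Region labels are metadata
#'   assigned by the experimenter, never inferred from the signals.
#' @param impedance_ohm impedance magnitude at 1 kHz, in ohms (recycled).
#' @param included logical inclusion flag (recycled).
#' @return data.frame with columns `channel_id`, `row`, `col`, `x_um`,
#'   `y_um`, `region`, `impedance_ohm`, `included`.
#' @export
channel_grid <- function(n_rows = 4, n_cols = 4, pitch_um = 500,
                         region = "cortex", impedance_ohm = 1.4e6,
                         included = TRUE) {
  n <- n_rows * n_cols
  rows <- rep(seq_len(n_rows) - 1L, each = n_cols)
  cols <- rep(seq_len(n_cols) - 1L, times = n_rows)
  ch <- data.frame(
    channel_id = seq_len(n),
    row = rows, col = cols,
    x_um = cols * pitch_um, y_um = rows * pitch_um,
    region = rep_len(as.character(region), n),
    impedance_ohm = rep_len(impedance_ohm, n),
    included = rep_len(as.logical(included), n),
    stringsAsFactors = FALSE
  )
  validate_channels(ch)
  ch
}

validate_channels <- function(ch) {
  need <- c("channel_id", "row", "col", "x_um", "y_um", "region",
            "impedance_ohm", "included")
  miss <- setdiff(need, names(ch))
  if (length(miss)) stopf("channel table lacks columns: %s",
                          paste(miss, collapse = ", "))
  if (!all(ch$region %in% REGION_LEVELS))
    stopf("region labels must be one of: %s", paste(REGION_LEVELS, collapse = ", "))
  if (any(ch$impedance_ohm <= 0)) stopf("impedance_ohm must be > 0")
  if (anyDuplicated(ch$channel_id)) stopf("duplicate channel_id")
  invisible(ch)
}

#' Stimulus protocol for pulsed photic stimulation
#'
#' Describes trains of light pulses: `onsets_s` holds the onset time of every
#' pulse (all trains concatenated), strictly increasing.
#'
#' @param onsets_s pulse onset times in seconds, strictly increasing.
#' @param pulse_width_s pulse duration (s); must satisfy
#'   `pulse_width_s <= 1 / pulse_rate_hz`.
#' @param pulse_rate_hz within-train pulse rate (Hz).
#' @param train_duration_s train length (s).
#' @param n_trials number of trains.
#' @return object of class `oe_stimulus`.
#' @export
stimulus_protocol <- function(onsets_s, pulse_width_s, pulse_rate_hz,
                              train_duration_s, n_trials) {
  if (length(onsets_s) && any(diff(onsets_s) <= 0))
    stopf("stimulus onsets must be strictly increasing")
  assert_scalar_num(pulse_width_s, "pulse_width_s", lo = 0)
  assert_scalar_num(pulse_rate_hz, "pulse_rate_hz", lo = 1e-9)
  if (pulse_width_s > 1 / pulse_rate_hz + 1e-12)
    stopf("pulse_width_s (%g) exceeds pulse period 1/pulse_rate_hz (%g)",
          pulse_width_s, 1 / pulse_rate_hz)
  structure(list(onsets_s = as.numeric(onsets_s),
                 pulse_width_s = pulse_width_s,
                 pulse_rate_hz = pulse_rate_hz,
                 train_duration_s = train_duration_s,
                 n_trials = as.integer(n_trials)),
            class = "oe_stimulus")
}

#' Multichannel recording bundle
#'
#' The central container: a channels x samples voltage matrix plus sampling
#' rate, channel metadata, optional stimulus protocol, brain-state label and
#' a free-text processing log.
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param fs_hz sampling rate (Hz), > 0.
#' @param channels channel metadata, as from [channel_grid()].
#' @param stimulus optional [stimulus_protocol()].
#' @param state `"awake"` or `"anesthetized"`.
#' @param provenance character vector of processing-log lines.
#' @return object of class `oe_recording`.
#' @export
recording <- function(data, fs_hz, channels, stimulus = NULL,
                      state = c("awake", "anesthetized"),
                      provenance = character()) {
  state <- match.arg(state)
  data <- as.matrix(data)
  assert_scalar_num(fs_hz, "fs_hz", lo = 1e-9)
  validate_channels(channels)
  if (nrow(data) != nrow(channels))
    stopf("data has %d rows but channel table has %d channels",
          nrow(data), nrow(channels))
  if (!is.null(stimulus) && !inherits(stimulus, "oe_stimulus"))
    stopf("stimulus must be an oe_stimulus or NULL")
  structure(list(data = data, fs_hz = fs_hz, channels = channels,
                 stimulus = stimulus, state = state,
                 provenance = as.character(provenance)),
            class = "oe_recording")
}

#' @export
print.oe_recording <- function(x, ...) {
  cat(sprintf("<oe_recording> %d channels x %d samples @ %g Hz (%.1f s), state=%s\n",
              nrow(x$data), ncol(x$data), x$fs_hz, ncol(x$data) / x$fs_hz, x$state))
  cat(sprintf("  regions: %s; included: %d/%d; stimulus: %s\n",
              paste(sprintf("%s=%d", names(table(x$channels$region)),
                            table(x$channels$region)), collapse = " "),
              sum(x$channels$included), nrow(x$channels),
              if (is.null(x$stimulus)) "none" else
                sprintf("%d pulses", length(x$stimulus$onsets_s))))
  invisible(x)
}

rec_duration <- function(rec) ncol(rec$data) / rec$fs_hz

log_step <- function(rec, fmt, ...) {
  rec$provenance <- c(rec$provenance, sprintf(fmt, ...))
  rec
}

#' Per-channel multi-unit event train
#'
#' @param channel_id integer channel label.
#' @param event_times_s strictly increasing event times (s).
#' @param threshold_multiplier detection threshold in units of the MUA
#'   standard deviation (negative, typically -3 to -4).
#' @param sd_estimate_uv the standard deviation estimate used (microvolts).
#' @return object of class `oe_event_train`.
#' @export
event_train <- function(channel_id, event_times_s,
                        threshold_multiplier = NA_real_,
                        sd_estimate_uv = NA_real_) {
  event_times_s <- as.numeric(event_times_s)
  if (length(event_times_s) && any(diff(event_times_s) <= 0))
    stopf("event times must be strictly increasing (channel %s)", channel_id)
  structure(list(channel_id = as.integer(channel_id),
                 event_times_s = event_times_s,
                 threshold_multiplier = threshold_multiplier,
                 sd_estimate_uv = sd_estimate_uv),
            class = "oe_event_train")
}

# ---------------------------------------------------------------------------
# Recording bundle on disk: a directory holding
#   meta.json     fs_hz, state, provenance, n_channels, n_samples, stimulus
#   channels.csv  channel metadata table
#   data.bin      little-endian float32, channel-major (each channel's
#                 samples contiguous), microvolts
# Self-describing and language-neutral; any float32 reader can consume it.
# ---------------------------------------------------------------------------

#' Write a recording bundle to disk
#'
#' Creates (or overwrites) a directory bundle holding the voltage matrix as
#' little-endian float32 plus JSON/CSV metadata. Voltages are quantized to
#' float32; repeated writes of the same recording are byte-identical.
#'
#' @param rec an [recording()].
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "oe_recording")) stopf("rec must be an oe_recording")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stopf("cannot create bundle directory '%s'", path)
  meta <- list(
    format = "orgephys-bundle-v1",
    fs_hz = rec$fs_hz,
    n_channels = nrow(rec$data),
    n_samples = ncol(rec$data),
    state = rec$state,
    provenance = as.list(rec$provenance)
  )
  if (!is.null(rec$stimulus)) {
    s <- rec$stimulus
    meta$stimulus <- list(onsets_s = as.list(s$onsets_s),
                          pulse_width_s = s$pulse_width_s,
                          pulse_rate_hz = s$pulse_rate_hz,
                          train_duration_s = s$train_duration_s,
                          n_trials = s$n_trials)
  }
  json <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, file.path(path, "meta.json"), useBytes = TRUE)
  utils::write.csv(rec$channels, file.path(path, "channels.csv"),
                   row.names = FALSE)
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  # channel-major: channel 1's samples first (t(data) flattens row-major)
  writeBin(as.vector(t(rec$data)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a recording bundle from disk
#'
#' Inverse of [write_recording()]. A bundle without a stimulus block yields
#' `stimulus = NULL`. Data round-trips exactly at float32 precision.
#'
#' @param path bundle directory.
#' @return an [recording()].
#' @export
read_recording <- function(path) {
  if (!dir.exists(path)) stopf("bundle '%s' does not exist", path)
  for (f in c("meta.json", "channels.csv", "data.bin"))
    if (!file.exists(file.path(path, f)))
      stopf("malformed bundle: missing %s", f)
  meta <- jsonlite::fromJSON(file.path(path, "meta.json"),
                             simplifyVector = TRUE)
  if (is.null(meta$fs_hz) || meta$fs_hz <= 0)
    stopf("invalid bundle: fs_hz must be > 0")
  ch <- utils::read.csv(file.path(path, "channels.csv"),
                        stringsAsFactors = FALSE)
  for (col in c("channel_id", "row", "col")) ch[[col]] <- as.integer(ch[[col]])
  for (col in c("x_um", "y_um", "impedance_ohm")) ch[[col]] <- as.numeric(ch[[col]])
  ch$included <- as.logical(ch$included)
  ch$region <- as.character(ch$region)
  validate_channels(ch)
  n_ch <- as.integer(meta$n_channels)
  n_s <- as.integer(meta$n_samples)
  if (n_ch != nrow(ch))
    stopf("malformed bundle: data declares %d channels but channels.csv has %d records",
          n_ch, nrow(ch))
  sz <- file.info(file.path(path, "data.bin"))$size
  if (sz != 4 * n_ch * n_s)
    stopf("malformed bundle: data.bin has %d bytes, expected %d", sz, 4 * n_ch * n_s)
  con <- file(file.path(path, "data.bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, what = "numeric", n = n_ch * n_s, size = 4L,
               endian = "little")
  data <- matrix(x, nrow = n_ch, byrow = TRUE)
  stim <- NULL
  if (!is.null(meta$stimulus)) {
    s <- meta$stimulus
    stim <- stimulus_protocol(as.numeric(unlist(s$onsets_s)),
                              as.numeric(s$pulse_width_s),
                              as.numeric(s$pulse_rate_hz),
                              as.numeric(s$train_duration_s), s$n_trials)
  }
  recording(data, as.numeric(meta$fs_hz), ch, stimulus = stim,
            state = meta$state,
            provenance = as.character(unlist(meta$provenance) %||% character()))
}

#' Write event trains to CSV
#'
#' One row per event, header `channel_id,time_s`, times printed with six
#' decimals (microsecond precision).
#'
#' @param trains list of [event_train()] objects.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_events <- function(trains, path) {
  if (inherits(trains, "oe_event_train")) trains <- list(trains)
  lines <- "channel_id,time_s"
  for (tr in trains) {
    if (!inherits(tr, "oe_event_train")) stopf("trains must be oe_event_train objects")
    if (length(tr$event_times_s))
      lines <- c(lines, sprintf("%d,%.6f", tr$channel_id, tr$event_times_s))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read event trains from CSV
#'
#' @param path CSV written by [write_events()].
#' @param channel_ids optional integer vector: channels that must appear in
#'   the result (empty trains for channels with no events).
#' @return list of [event_train()] objects, one per channel present (plus any
#'   requested empty channels), ordered by channel id.
#' @export
read_events <- function(path, channel_ids = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("channel_id", "time_s") %in% names(df)))
    stopf("event file must have header channel_id,time_s")
  ids <- sort(unique(c(df$channel_id, channel_ids)))
  lapply(ids, function(id) {
    tt <- df$time_s[df$channel_id == id]
    if (length(tt) && any(diff(tt) <= 0))
      stopf("event times for channel %d are not strictly increasing", id)
    event_train(id, tt)
  })
}
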