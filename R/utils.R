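# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stopf("'%s' must be a finite number in [%s, %s]", name, lo, hi)
  invisible(x)
}

# Indices of channels flagged as included; used by every downstream statistic
# so that excluded channels never contribute.
included_idx <- function(rec) which(rec$channels$included)

# Deterministic 32-bit integer seed derived from a master seed and a stage
# label, so stage-level randomness is reproducible independent of run order.
derive_seed <- function(master_seed, stage) {
  h <- as.double(master_seed %% 2147483647L)
  for (code in utf8ToInt(as.character(stage))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# jsonlite wrapper with the conventions used for all reports.
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

next_pow2 <- function(n) 2^ceiling(log2(n))
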