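# Shared configuration for the analysis scripts. Sourced by every driver.
#
# The study conditions mirror the recorded regime at a desk-friendly scale:
# a 4 x 4 grid at 500 um pitch sampled at 20 kHz, trains of 100-ms light
# pulses at 2 Hz, evoked amplitudes ~200 uV near visual cortex decaying to
# ~50 uV over the organoid, a 36 ms base latency with up to 5.7 ms extra
# delay across the grid, ~2 Hz spiking locked to 5 Hz theta during
# stimulation, a shared motion-artifact source, and 60 Hz line noise.

library(orgephys)

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

MASTER_SEED <- 20260926L

# 10 trials of 4-s trains keep each script in the tens of seconds; the full
# 20-trial protocol only changes statistical resolution, not structure.
study_spec <- synth_spec(
  fs_hz = 20000,
  seed = MASTER_SEED,
  stimulus = list(n_trials = 10, train_duration_s = 4, pulse_rate_hz = 2,
                  train_period_s = 6.1, lead_s = 2),
  spikes = list(rate_hz = 2, amp_sd = 6, kappa = 2, lock_freq_hz = 5, mu = pi),
  anesthesia = list(duration_s = 60)
)

path_raw <- file.path(RESULTS_DIR, "raw_bundle")
path_clean <- file.path(RESULTS_DIR, "clean_bundle")
path_events <- file.path(RESULTS_DIR, "mua_events.csv")

say <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...))
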