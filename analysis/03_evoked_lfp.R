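#!/usr/bin/env Rscript
# Stimulus-evoked LFP: trial averages, peak amplitude/delay maps, and the
# shuffle test for an organoid-to-cortex propagation delay.

source("analysis/00_config.R")

rec <- read_recording(path_clean)
lfp <- filter_lfp(rec)
tt <- epoch_trials(lfp, which_pulse = 1, pre_s = 0.2, post_s = 0.5)
say("Epoched %d trials around the first pulse of each train.", tt$n_trials)

ta <- trial_average(tt)
pm <- peak_map(ta, search_window_s = c(0.01, 0.08), polarity = "negative")
utils::write.csv(pm, file.path(RESULTS_DIR, "peak_map.csv"), row.names = FALSE)

truth <- jsonlite::fromJSON(file.path(RESULTS_DIR, "ground_truth.json"))
say("Peak delays span %.2f-%.2f ms post-onset (injected gradient up to %.1f ms",
    1000 * min(pm$peak_delay_s, na.rm = TRUE),
    1000 * max(pm$peak_delay_s, na.rm = TRUE),
    max(truth$true_delays_ms))
say("on top of the 36 ms base latency). Note that removing the strictly")
say("uniform shared component also subtracts the evoked common mode, which")
say("compresses delay magnitudes; the ordering survives.")

ok <- pm$included & !is.na(pm$peak_delay_s)
ref <- pm$channel_id[ok][which.min(pm$peak_delay_s[ok])]
far <- pm$channel_id[ok][which.max(pm$peak_delay_s[ok])]
ds <- delay_shuffle_test(pm, ref, far, n_shuffles = 1000,
                         seed = MASTER_SEED + 3)
say("Extreme pair %d -> %d: delta = %.2f ms, shuffle-null t = %.2f, p = %.4g",
    ref, far, 1000 * ds$observed_delta_s, ds$t, ds$p_value)
jsonlite::write_json(c(list(ref_channel = ref, far_channel = far), ds),
                     file.path(RESULTS_DIR, "delay_test.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
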