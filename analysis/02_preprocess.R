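#!/usr/bin/env Rscript
# Channel exclusion and removal of shared (volume-conducted) components.

source("analysis/00_config.R")

rec <- read_recording(path_raw)
rec <- exclude_channels(rec, max_impedance_ohm = 4e6)
say("%d/%d channels included after the 4 MOhm impedance screen.",
    sum(rec$channels$included), nrow(rec$channels))

# The shared subspace is estimated on inter-trial segments so the evoked
# responses (correlated but locally generated) cannot leak into it.
excl <- cbind(rec$stimulus$onsets_s - 0.01, rec$stimulus$onsets_s + 0.6)
out <- remove_common_components(rec, uniformity_cv_max = 0.25,
                                exclude_windows_s = excl)
say("JADE removed %d of %d components (mixing-weight CV <= 0.25, same sign): %s",
    length(out$report$removed_component_indices), out$report$n_components,
    paste(out$report$removed_component_indices, collapse = ", "))
say("Fraction of total variance removed: %.3f",
    out$report$variance_removed_fraction)

write_recording(out$recording, path_clean)
jsonlite::write_json(out$report, file.path(RESULTS_DIR, "ica_report.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
say("Clean bundle written to %s", path_clean)
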