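Package: orgephys
Title: Multichannel Electrophysiology Analysis for Cortical Organoid Implants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multichannel extracellular recordings from
    microelectrode arrays implanted over cortical organoid grafts and host
    cortex. Provides a synthetic recording generator with known ground truth,
    channel exclusion and JADE-based removal of shared (volume-conducted)
    components, zero-phase Chebyshev band extraction of local field potentials
    and multi-unit activity, stimulus-evoked LFP latency maps with a
    shuffle-based propagation-delay test, Morlet wavelet spectrograms and
    band-power contrasts between brain states, threshold-based multi-unit
    event detection with shift-permutation co-occurrence nulls, and multitaper
    spike-field phase-locking statistics with bootstrap confidence intervals
    and Rayleigh tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
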