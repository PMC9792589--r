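# orgephys

Analysis of multichannel extracellular recordings from microelectrode
arrays implanted over cortical organoid grafts and surrounding host cortex.

## The scientific problem

A human cortical organoid transplanted into rodent cortex under a
transparent 4 × 4 microelectrode grid (500 µm pitch, 20 kHz sampling)
raises the question: does the graft *functionally* integrate with the host
visual network? The electrophysiological case for integration rests on a
small set of analyses, and this package implements all of them as tested,
reusable stages over a common recording container:

* **Evoked LFP propagation** — trial-averaged biphasic responses to light
  pulses; per-channel peak amplitude/latency maps; a channel-shuffle null
  test for the propagation delay between a cortex-proximal and an
  organoid channel (synaptic propagation lags by milliseconds; volume
  conduction does not).
* **Spectral structure** — Morlet wavelet spectrograms (unit-energy
  wavelets, so power is a per-Hz density), band-power tables, power at the
  stimulation frequency and its second harmonic, induced gamma at pulse
  onset, and the awake-vs-anesthetized organoid/cortex band-power ratio
  with a one-sided two-sample t test.
* **Multi-unit activity** — 0.5–3 kHz zero-phase Chebyshev band, negative
  threshold-crossing event detection (−3…−4 sd), rectified-and-smoothed
  MUA power with evoked SNR in dB, event-triggered average waveforms as a
  locality check, and 1-ms-bin event co-occurrence against a
  10,000-circular-shift permutation null.
* **Spike–field phase locking** — sliding-window multitaper phase (DPSS
  tapers, 1-s windows), PLV = |circular mean of phases at event times|,
  bootstrap confidence intervals from resamples of 50 events,
  stim/no-stim significance flags, Rayleigh tests, and the spatial theta
  PLV map across the grid.

Preprocessing excludes channels above 4 MΩ impedance and removes shared
(volume-conducted) components with an in-package, deterministic JADE
implementation: components whose mixing weights are near-uniform
(coefficient of variation ≤ 0.25) and sign-consistent across channels are
zeroed, estimated on 250 Hz-decimated inter-trial data and removed from
the broadband signal.

For the phase statistics at the core of the package: MUA events at times
\(t_j\) with LFP phases \(\phi(t_j, f)\) give

PLV(f) = | (1/n) Σ_j exp(i φ(t_j, f)) | ∈ [0, 1],

estimated by bootstrap resamples of 50 events; for spikes locked with a
von Mises(μ, κ) phase distribution the population value is the Bessel
ratio I₁(κ)/I₀(κ), which the synthetic ground truth records and the tests
recover to ±0.05. Circular uniformity is tested with Rayleigh's
Z = nR².

Because the underlying animal recordings are not publicly deposited, the
package ships a first-class synthetic generator (`generate_recording()`,
`generate_anesthesia_epoch()`) that produces recordings with the assumed
statistical structure — evoked delay gradients, induced gamma, a locally
graded theta rhythm, von Mises-locked spikes, a shared motion-artifact
source, 60 Hz line noise, burst suppression — together with the injected
ground truth, so every stage is validated by parameter recovery and
calibration rather than by re-asserting printed numbers.

## Worked example

The `analysis/` directory is a numbered workflow over the package
(`01_simulate.R` … `08_pipeline.R`); each script prints what it found and
writes tables under `results/`. Running them in order on the default
conditions produces (abridged, actual output):

```
== 02_preprocess ==
JADE removed 1 of 16 components (mixing-weight CV <= 0.25, same sign): 1
== 03_evoked_lfp ==
Extreme pair 1 -> 8: delta = 2.50 ms, shuffle-null t = 3.13, p = 0.001777
== 05_mua ==
Detected MUA events at -4 sd; spontaneous (no-stim) rates 0.96-2.05 Hz (median 1.47).
Evoked MUA SNR: 1.2 dB (min) to 1.6 dB (max) across channels.
Spontaneous events, channels 7 vs 12: 1 overlapping 1-ms bins; shift-null
p = 0.135 (within chance, as for locally generated activity)
== 06_phase_locking ==
Theta (4-6 Hz) PLV: 0.58 during stimulation vs 0.17 without; difference
significant (95% bootstrap CI).
Rayleigh test at 5 Hz, n = 382 stim events: R = 0.62, Z = 145.9, p = 1.39e-71.
== 07_anesthesia ==
anesthetized: ... low_gamma=0.52* high_gamma=0.52*
awake:        ... low_gamma=1.02  high_gamma=1.03
== 08_pipeline ==
Report hash: 9bbc09aee91d5da2d8b60ec43114f647 (rerun identical: TRUE)
```

Reading these numbers: the shared motion-artifact component was identified
and removed (1 of 16); the evoked peak lags the cortex-proximal corner by
2.5 ms with the shuffle null rejecting exchangeability (p ≈ 0.002) — note
that removing the strictly uniform shared component also subtracts the
evoked common mode, which compresses the apparent delay magnitude
(injected: 5.7 ms) while preserving its ordering and significance;
spontaneous multi-unit rates sit in the ~2 Hz regime and do not co-occur
across channels beyond chance (locality), while theta phase locking
roughly triples during stimulation and is flagged by the bootstrap CI; the
organoid/cortex gamma power ratio drops to ≈ 0.5 only under anesthesia
(generator truth: 0.5); and the orchestrated pipeline is bit-reproducible
under a fixed master seed.

The same stages are available programmatically:

```r
library(orgephys)
gen <- generate_recording(synth_spec(seed = 1))
rec <- exclude_channels(gen$recording)
rec <- remove_common_components(rec)$recording
pm  <- peak_map(trial_average(epoch_trials(filter_lfp(rec))))
delay_shuffle_test(pm, chan_a = 16, chan_b = 1, n_shuffles = 1000, seed = 1)
```

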