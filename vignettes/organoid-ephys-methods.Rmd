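---
title: "Methods: multichannel electrophysiology analysis for organoid implants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multichannel electrophysiology analysis for organoid implants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A cortical organoid grafted into rodent cortex under a transparent 4 x 4
microelectrode grid (500 µm pitch, 20 kHz sampling) raises one central
question: does the graft *functionally* integrate with the host sensory
network? The electrophysiological evidence for integration rests on four
analyses, each of which this package implements as a tested, reusable stage:

1. **Evoked LFP propagation.** Visual stimulation evokes biphasic local
   field potentials; if the graft is synaptically driven by visual cortex,
   its evoked peaks should *lag* the cortex-proximal channels by a few
   milliseconds (axonal conduction), whereas volume conduction is
   effectively instantaneous. Peak amplitude/latency maps plus a
   channel-shuffle null test quantify this.
2. **Spectral responses.** Morlet spectrograms show power at the
   stimulation frequency and its second harmonic, and induced gamma
   (60-100 Hz) at pulse onsets -- a localized signal, so its presence on
   graft channels argues for locally generated activity.
3. **Multi-unit locality and modulation.** MUA events (negative threshold
   crossings in the 0.5-3 kHz band) must be local to single channels
   (event-triggered averages flat elsewhere; 1-ms-bin co-occurrence within
   the shift-permutation chance band), yet their *timing* should be
   modulated by the shared network rhythm.
4. **Spike-field phase locking.** The phase-locking value (PLV) of MUA
   events to the theta-band LFP phase, with bootstrap confidence intervals
   and Rayleigh tests, measures that modulation; the stimulus-conditioned
   increase and its spatial map toward visual cortex are the headline
   integration signature.

Because the underlying animal recordings are not publicly deposited, every
stage is validated against a synthetic-data generator with known ground
truth; the package's claims are therefore *property* claims (parameter
recovery, calibration, locality) rather than reproductions of the printed
animal-study numbers.

## Data model and units

A `recording` is a channels x samples matrix in microvolts with sampling
rate, per-channel metadata (grid position, region label
organoid/cortex/ambiguous, 1 kHz impedance, inclusion flag), an optional
pulse-train stimulus protocol, and a processing log. Region labels are
experimenter metadata, never inferred. Time is in seconds with sample 0 at
t = 0; windows are half-open `[start, end)`. On disk a recording is a
directory bundle (`meta.json`, `channels.csv`, little-endian float32
`data.bin`), chosen as a self-describing, language-neutral format that any
float32 reader can consume; voltages round-trip exactly at float32
precision. Event trains are plain CSV (`channel_id,time_s`, microsecond
precision).

## The synthetic generator

`generate_recording()` composes, per channel:

* background noise: white Gaussian + 1/f (spectral exponent 1) + a
  Laplace-distributed broadband "hash" term. The hash term models the
  heavy-tailed background of distant multi-unit activity; it also gives
  each channel's local signal the non-Gaussianity that fourth-order blind
  source separation needs to be identifiable (with purely Gaussian
  backgrounds *any* rotation of the noise subspace is a valid ICA
  solution, and uniformity-based component selection becomes arbitrary);
* stimulus-evoked biphasic LFP kernels whose (negative) peak latency is
  `latency0 + delay_max * d/d_max`, `d` the Euclidean distance from the
  visual-cortex-proximal corner, and whose amplitude decays linearly from
  200 µV to 50 µV across the grid -- the printed evoked regime (36 ms base
  latency, 5.7 ms maximal extra delay);
* induced gamma bursts (80 Hz, 150 ms) at each pulse onset with a *random
  carrier phase per pulse*: induced (non-phase-locked) gamma contributes
  power to single-trial spectrograms but averages out of the evoked
  waveform, so it cannot bias peak-latency maps;
* an ongoing 5 Hz theta rhythm whose amplitude decays with distance from
  the reference corner (a locally generated rhythm with a spatial
  gradient -- a spatially uniform oscillation would be indistinguishable
  from volume conduction and correctly removed in preprocessing);
* Poisson spike trains (biphasic 0.4 + 0.6 ms kernels, amplitudes stated
  in units of the channel's MUA-band noise sd and calibrated *after* the
  band-pass, so "-6 sd spikes" means -6 sd in the analyzed band) whose
  phases follow a von Mises distribution around the theta trough. Locking
  is stimulus-gated by default: concentration `kappa` inside
  `[onset, onset + width + 0.1 s)`, `kappa_no_stim = 0` elsewhere, which
  is the contrast the stim/no-stim PLV comparison detects. Each light
  pulse additionally drives an evoked multi-unit burst (`evoked_rate_hz`,
  default 60 Hz of extra locked firing during the pulse), the source of
  the evoked MUA power response; spontaneous rates are quoted outside the
  pulse windows. The ground truth records the population PLV
  `I1(kappa)/I0(kappa)`;
* a shared component with identical weight on all channels, modeled as a
  sparse Poisson train of signed raised-cosine transients (awake motion
  artifacts). Sparseness matters twice: it is what shared artifacts look
  like, and it keeps the source kurtotic at LFP timescales, hence
  identifiable after the 250 Hz estimation decimation (a low-passed
  Gaussian shared source is provably unseparable from Gaussian channel
  noise by any cumulant-based method);
* 60 Hz line noise, also uniform across channels.

Default trains are 20 repetitions of 4-s, 2 Hz trains of 100-ms pulses.
The inter-train period is 6.1 s, deliberately incommensurate with 5 Hz so
the theta rhythm is not phase-locked to trial onsets (a 6.0 s period locks
theta to the trial average and biases peak maps).

`generate_anesthesia_epoch()` produces burst suppression: alternating
whole-second burst/suppression segments (suppression fraction 0.5 by
default, mean cycle 4 s), a 2% envelope floor with 10 ms ramps, burst
content of per-channel 1/f noise plus narrowband gamma (45 and 80 Hz). On
organoid channels the gamma amplitude is scaled by `sqrt(gamma_power_scale)`
(default power scale 0.5) only in the anesthetized state -- the
region-by-state contrast the band-power comparison recovers. Whole-second
segment lengths make the realized suppression fraction recoverable by 1-s
RMS windowing without boundary bias.

**What the generator does not emulate:** biophysical dynamics (no
compartmental or network model), electrode drift, spike-waveform diversity
or bursting, state transitions within an epoch, and any nonstationarity of
the evoked response over sessions. Passing tests therefore demonstrate that
the *analysis* recovers what it claims from signals with the assumed
statistical structure -- not that real tissue has that structure.

## Preprocessing

Channels with 1 kHz impedance above 4 MΩ are excluded (flag only; excluded
channels never enter any downstream statistic, which a poisoned-channel
test enforces).

Shared (volume-conducted) components are removed with JADE -- joint
diagonalization of fourth-order cumulant matrices -- written in-package and
deterministic, so the preprocessing stage needs no seed. The decomposition
is estimated on data decimated to 250 Hz (the shared sources of interest
are LFP-band), and with a stimulus present, on inter-trial segments only:
evoked responses are correlated across channels but locally generated, and
estimating on spontaneous segments keeps them out of the removed subspace.
Removal is then applied to the broadband signal through the estimated
mixing, leaving the MUA band intact.

A component is classified as shared when (i) the coefficient of variation
of its absolute mixing weights across channels is at most 0.25, (ii) the
weights are sign-consistent (volume conduction is same-polarity by
physics), and (iii) it is among the `max_components = 3` most uniform
candidates. Guards (ii) and (iii) exist because with largely Gaussian
backgrounds the ICA rotation within the Gaussian subspace is arbitrary and
can produce many same-sign, near-uniform mixing columns; removing them all
deletes 40-55% of the variance and, more damagingly, the common mode of
the evoked response. Explicit component indices can override the rule.

**Known limitation.** Even a perfectly targeted removal of a strictly
uniform component subtracts the *common mode* of a traveling evoked wave
(all channels deflect with the same sign), which compresses apparent delay
magnitudes while preserving their ordering and the shuffle-test
significance. The exact-recovery test for delays is therefore run on the
noiseless construction without a shared source, as an identity check of
the epoching/peak machinery; the full pipeline asserts ordering and
significance, not magnitude.

Band extraction uses Chebyshev type II filters with 40 dB stopband
attenuation, applied forward-backward (zero phase; stated orders are
design orders before the double pass): LFP = 8th-order low-pass with
stopband from 300 Hz; MUA = 6th-order band-pass with stopbands at 250 Hz
and 6 kHz (1 kHz passes within 1%, 10 Hz and 6 kHz are ≥ 40 dB down after
the double pass). Type II keeps the passband flat, protecting
amplitude-based peak maps.

## Evoked LFP analysis

Trials are epochs `[-pre, post)` around the chosen pulse of each train
(exact slicing, verified bit-for-bit). Peak maps take the extremum of the
chosen polarity (default negative, the first evoked deflection) of the
trial-averaged trace inside a search window of 10-80 ms post onset --
bracketing the ~36-42 ms latencies while excluding the stimulus artifact --
with amplitude relative to the pre-onset baseline mean (the baseline
convention is ours; the alternative, amplitude relative to zero, changes
amplitudes but not delays).

The delay test permutes the per-channel delay values 1000 times,
recomputes the pair difference, and refers the observed difference to the
null sample's mean and sd through a t statistic with `n_shuffles - 1`
degrees of freedom. Two details matter. First, the t statistic uses the
null *sd*, not the sd of the null mean: dividing by `sd/sqrt(n_shuffles)`
would reject iid delays ~95% of the time, while the sd-form is calibrated
(rejection at the nominal 5% under exchangeable delays, verified at 500
replicates). Second, both one- and two-sided p-values are exposed: the
methodological description of the source study states a two-sided test
while its results quote a one-tailed one, so neither is guessed as
canonical; the injected gradient is significant under both.

## Spectral analysis

Morlet wavelets with 7 cycles at every analysis frequency (log grid
1-150 Hz by default), implemented in the frequency domain with unit
discrete L2 energy per wavelet, so squared magnitude is a power *density*:
white noise is flat across analysis frequencies (tested to ±20%), band
means are comparable across bands, and amplitude scaling is exactly
quadratic. Trial-averaged spectrograms average single-trial power, so
induced (non-phase-locked) responses survive. Band edges default to delta
1-4, theta 4-8, alpha 8-12, beta 12-30, low gamma 30-60, high gamma
60-150 Hz; only the theta (4-6 for PLV) and gamma conventions are printed
in the source study, the rest are standard conventions and configurable.

`region_power_ratio()` normalizes each band's mean organoid power by the
mean cortex power and tests organoid < cortex across channels with a
one-sided two-sample t test (6 vs 8 channels in the default layout). The
ratio and p-values are scale-invariant.

## MUA analysis

MUA power = full-wave rectification then zero-phase low-pass below 100 Hz
(a 1 kHz tone of amplitude A gives the analytic 2A/π). Evoked SNR =
`10*log10(peak trial-averaged power in the response window / mean power
over the 1 s before onset)`.

Events are negative-going crossings of `-k` times the channel sd computed
over the whole trace (plain sd to match the stated convention; a
MAD-based robust option exists), with a 1 ms dead time matching the
overlap bin width. Detection counts are monotone non-increasing in `k`,
and the false-event rate of band-limited Gaussian noise follows the Rice
level-crossing rate `nu0 * exp(-k^2/2)` with `nu0` the RMS frequency of
the realized filter response (tested at ±50%). A consequence worth
stating plainly: for noise confined to 0.5-3 kHz, `nu0` is 1.4-1.9 kHz, so
even at `k = 4` noise crossings arrive at ~0.5 Hz; against 2 Hz true
spikes, detection *precision* cannot exceed roughly 0.8 regardless of
implementation, although recall for -6 sd spikes exceeds 0.95. The
pipeline defaults to `k = 4` (the conservative end of the -3..-4 range,
as chosen "depending on recording SNR") because looser thresholds admit
enough unlocked noise events to dilute event-conditioned statistics like
the stimulus-locked PLV contrast.

Co-occurrence bins events into half-open 1-ms bins aligned to t = 0
(binary occupancy) and counts jointly occupied bins; the null circularly
shifts one train 10,000 times, uniformly on `(1 s, T - 1 s)` to preserve
each train's autostructure. The p-value uses the add-one correction
`(1 + #{null >= obs})/(1 + n_shifts)` (the plain ratio is also reported).
Because the overlap count is a small integer, the add-one p-value is
discrete and conservative; the result therefore also carries the standard
randomized (tie-broken) p-value, which is exactly uniform under
independence and is the right quantity for calibration diagnostics --
rejection rates use the add-one form, uniformity checks the randomized
form.

## Phase locking

Phases come from a sliding multitaper estimate: 1-s windows every 50 ms,
DPSS tapers (computed by the standard tridiagonal eigendecomposition) with
time-bandwidth 3 and 5 tapers (the low end of the stated 3-5 / 5-9
ranges), zero-padding to twice the next power of two. Per window the
per-taper spectra are combined as a weighted complex mean with weights
`V_k(0)` (each taper's kernel at zero offset) -- Thomson's line-component
estimator. The unweighted complex mean carries a quadrature phase bias of
up to ~0.17 rad whenever a frequency falls between FFT bins (antisymmetric
tapers contribute a purely imaginary kernel), which would violate the
package's own 0.05 rad phase contract; the weighted form recovers a
tone's phase essentially exactly, at the cost of down-weighting the
antisymmetric tapers' variance reduction. Phases are referenced to the
window centre, and event lookup advances the nearest-centre phase by
`2*pi*f*dt` to the event time -- without this the ±25 ms lookup jitter
multiplies a 5 Hz PLV by sinc ≈ 0.90, breaking recovery at the ±0.05
tolerance.

PLV is the magnitude of the circular mean of unit phasors at event times.
`plv_bootstrap()` draws 1000-2000 resamples of 50 events with replacement
(sample size shrinks, flagged, for sparser trains); the point estimate is
the resample mean and the CI the 2.5/97.5 percentiles. The fixed resample
size equalizes the finite-sample bias across conditions; the cost is a
positive floor -- uniform phases give resultants concentrating near
`sqrt(pi/(4*50)) ≈ 0.125`, never 0 -- so a CI can never cover a true PLV
of 0, and calibration statements at `kappa = 0` are made against that
floor, not against 0. Condition comparison pairs the two conditions'
independent resample streams and flags frequencies whose difference CI
excludes 0 (a CI-overlap rule is available and more conservative; the
source study's wording does not disambiguate the two). The stim/no-stim
event partition assigns events within `[onset, onset + pulse width +
100 ms)` to the stimulated condition; the partition rule is not printed in
the source study and is configurable. Rayleigh tests use
`Z = nR^2` with the standard series approximation for p, calibrated at
n = 67 against 10,000 uniform replicates.

## Pipeline and reproducibility

`run_pipeline()` chains simulate/load → preprocess → evoked LFP → spectra
→ MUA → PLV → anesthesia contrast from one config. Every stochastic stage
derives its seed as a stable hash of (master seed, stage name), so stage
results do not depend on which other stages are enabled; JADE is
deterministic by construction. The JSON report is identical across reruns
of the same config (MD5 asserted in tests). Problem sizes used by the test
suite and the acceptance script are scaled-down study conditions chosen so
each property is measurable in seconds to a few minutes: e.g. 120 s
single-channel recordings for PLV recovery, 20 noiseless trials for delay
recovery, 100-200 replicates for calibration checks, 6-10 trials for
end-to-end runs; the vignetted defaults (20 trials) are used for the
single full-protocol integration run.

## Numerical choices and degenerate inputs

Zero-phase filtering throughout (forward-backward); flat traces yield NA
peaks rather than arbitrary extrema; flat channels yield empty event
trains with a warning; an all-equal delay map gives a 0/0-free t = 0 and
p = 1; empty trains give p = 1 with a warning in the shift test; Bessel
ratios use exponentially scaled Bessel functions for large kappa; the von
Mises sampler is Best-Fisher rejection; bootstrap and permutation RNG is
seeded everywhere and every generator output is deterministic given its
seed.

## Known limitations

* Uniform-component removal compresses evoked delay magnitudes (common-mode
  subtraction); ordering and significance survive.
* Detection precision is bounded near 0.8 by Rice-rate noise crossings in
  the MUA band at k ≤ 4 (see above); this is a property of threshold
  detection, not of the implementation.
* The spatial PLV map inherits the resample-size floor: channels without a
  locking rhythm sit near 0.125, not 0.
* ICA identifiability rests on non-Gaussian structure; on strictly
  Gaussian data the uniformity rule would select arbitrary components,
  which the sign-consistency and max-components guards bound but do not
  eliminate.
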