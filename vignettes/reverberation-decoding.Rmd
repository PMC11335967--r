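---
title: "Synthesizing reverberation and decoding its perception: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing reverberation and decoding its perception: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(reverbdecode)
```

This vignette explains the models and procedures the package implements,
the parameters that matter, and the choices made where the design was
genuinely open. It states no empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Impulse-response model

A reverberant impulse response (IR) is modelled as broadband Gaussian noise
decomposed into cochlear subbands, each multiplied by an amplitude
envelope, and summed. The subband statistics are held by a
`decay_profile`: per-band RT60 (seconds for band energy to fall 60 dB),
per-band initial level (dB), and the early-reflection cutoff marking where
the fitted reverberant tail begins.

**Filterbank.** `design_filterbank()` places `n_bands` (default 32)
half-cosine bandpass filters with equal spacing on the ERB-rate scale, the
standard auditory approximation to cochlear spacing, between `f_lo` (20 Hz)
and `f_hi` (10 kHz) at a 20 kHz sampling rate. Adjacent rising/falling
ramps are sin/cos complements, so squared gains sum to one and the
decomposition inverts by filtering each subband a second time and summing.
The first band extends flat to DC and the last to Nyquist (low-/high-pass
caps). This matters numerically: a sharp spectral edge at `f_lo` rings as
1/t in time, and that ringing of the loud IR onset would bury the decaying
tail of the lowest band, biasing its RT60 estimate enormously. Filtering is
done in the FFT domain with zero padding to twice the signal length,
because circular filtering would wrap the onset into the tail with the
same effect.

**Variants.** `transform_profile()` turns a profile into per-band
envelopes on the IR time grid: `ecological` imposes
`level * 10^(-3 t / RT60)` per band (amplitude −60 dB at `t = RT60`);
`linear_decay` replaces each exponential with a straight line hitting zero
at the band's −60 dB time; `time_reversed` reverses the ecological
envelopes in time (an exact involution); `flat_spectral` assigns every
band the level-weighted mean decay rate in dB/s, so across-band RT60
variance is zero by construction; `inverted_spectral` remaps decay rates
onto a concave template `sin(pi (k - 1/2) / K)` peaking at mid bands,
rescaled to preserve the across-band mean and spread of the original
rates, so middle frequencies decay fastest. The template choice is a
design decision — only the qualitative outcome (mid faster than lows and
highs) is prescribed — and rates are floored so no band's RT60 exceeds
8 s.

**Real-world-like profiles.** `real_profile()` emulates recorded rooms:
RT60 falls smoothly with frequency (total spread 0.4 octaves, low bands
slowest) and levels tilt −9 dB across the bank. Because the broadband
Schroeder decay of a band mixture is dominated late by the slow, loud
bands, the per-band targets are calibrated by a closed-form model of the
mixture energy-decay curve so that the *broadband* RT60 measured from the
synthesized IR matches the requested target; three fixed-point iterations
suffice.

**RT60 estimation.** `measure_rt60()` uses Schroeder backward integration
of squared amplitude after the direct-path peak, fitting the −5..−35 dB
span of the energy-decay curve and extrapolating to −60 dB. Rising or
non-decaying energy (e.g. a time-reversed IR) is flagged invalid rather
than fitted. `estimate_decay_profile()` applies the same fit per subband
after skipping `early_cutoff` (default 50 ms) past the peak, standing in
for the omission of early reflections.

**Resolution limit.** Adjacent cochlear bands overlap by construction, so
a band that decays much faster than its neighbours inherits their late
energy and its estimated RT60 is biased upward. Generate-then-estimate
round trips are therefore accurate (mean band error below 10%) for
profiles that vary smoothly across bands — the physically relevant case —
but not for arbitrary, discontinuous profiles. The lowest band also has
few independent noise degrees of freedom per realization (bandwidth times
duration), so single-realization estimates there are noisy; averaging a
few synthesis seeds stabilises them.

## 2. Stimulus construction

`convolve_and_segment()` performs full linear convolution of a dry source
with an IR, locates the maximal-amplitude sample within the first
1,000 ms, and extracts the 2 s segment starting 100 ms before that peak
(clipped at the signal start; the peak-to-segment alignment is otherwise
unspecified and 100 ms keeps the direct-sound onset inside the segment).
Raised-cosine 5 ms on/off ramps are applied *before* RMS equalisation so
the equated RMS is exact to 1e−6 while the first and last samples are
exactly zero.

The default `build_stimulus_set()` preset uses 30 room profiles, 10
sources through each real-like IR and 2 through each of the 5 variant IRs
— 600 stimuli, 300 real / 300 fake, every source unique. (A smaller
source-per-room count cannot reach those totals; the preset enforces the
totals.) Sources are drawn alternately from the two speaker pools so the
speaker attribute is balanced within class by construction, which is what
makes class statistically independent of duration, RMS, and speaker.
`schedule_blocks()` assigns stimuli to 10 blocks of 60 with equal class
counts per block and applies a ±1 dB uniform per-trial intensity jitter at
schedule time (stimulus files keep their equated RMS).

## 3. Synthetic EEG and behavior

`simulate_eeg_epochs()` generates trials × channels × time arrays at
1,000 Hz over −400..2,500 ms: spatially correlated 1/f background noise
(per-channel SD 4 µV, exponent 1, exponential channel-correlation kernel
with scale 0.5 head radii) plus white sensor noise (1 µV), plus, per
effect, a class-contingent pattern: a raised-cosine bump over the effect
window times a channel topography, with sign ±½ by class and a lognormal
per-subject amplitude jitter (σ = 0.2). The defaults place a 1.5 µV early
effect (470–960 ms) on the bilateral temporal cluster and a 1.5 µV late
effect (2,110–2,500 ms) on the centroparietal cluster, emulating the
two-stage structure the pipeline is designed to detect. The noise model is
the minimal realistic null — real EEG adds artifacts, nonstationarity,
and richer spatial structure, so passing tests show pipeline correctness
and calibration, not real-data performance.

`simulate_behavior()` draws independent Bernoulli correctness per trial
with per-variant probabilities; the reported label equals the physical
label when correct and the opposite otherwise. Defaults: real 0.8195,
ecological 0.52, linear decay 0.83, time reversed 0.96, flat spectral
0.55, inverted spectral 0.61, giving a fake mean of 0.6943 and 75.7%
overall under the balanced design.

**Sensor layout.** `sensor_layout_1020()` builds a 56-channel modified
10-20 montage from spherical coordinates (intermediate rows on
great-circle arcs), projected stereographically (radius
`tan(inclination/2)`). The montage deliberately omits the 10-10
intermediates (C5/C6, FT7/FT8, TP7/TP8, CP3/CP4, CPz, POz, ...), as on
common research caps; with them present no neighborhood radius isolates
the canonical clusters. `preset_sensor_clusters()` then selects, by 2-D
projected distance, the 12-channel bilateral temporal cluster around
T7/T8 (radius 0.60 head radii) and the 6-channel centroparietal cluster
around Pz (radius 0.43).

## 4. Preprocessing

The chain is common-average re-reference → baseline correction
(−200..0 ms; the window is a package default, configurable) → 10 ms boxcar
downsampling (each output sample is the mean of a nonoverlapping bin,
timestamped at the bin's left edge: 2,900 samples become 290 at 100 Hz) →
30 Hz low-pass (4th-order Butterworth, forward–backward for zero phase).
Filtering after downsampling is unconventional but follows the analysis
convention this pipeline reproduces; at these rates the 30 Hz cutoff sits
below the 50 Hz Nyquist. Re-referencing and baseline correction are
idempotent and satisfy exact zero-mean post-conditions.

One consequence worth knowing: common-average re-referencing redistributes
any class effect across all channels (a topography on k of n channels
leaks −k/n of its mean onto the rest), so with small montages a
cluster-confined effect becomes weakly decodable elsewhere. The bundled
56-channel montage keeps this leakage small but nonzero.

## 5. Decoding

For decoded time `t`, features are the sensor patterns at samples
`[t − lookback, t]` (inclusive; default lookback 20 samples = 200 ms, so
21 samples — 63 channels give 1,323 features) stacked channel-major by
time. The first decodable point of a −400 ms epoch is therefore −200 ms.
Per subaverage permutation, each class's trials are randomly assigned to
`n_subsets` (10) near-equal subsets and averaged into pseudo-trials;
cross-validation holds out one pseudo-trial per class per fold. The
classifier is a linear soft-margin SVM (C = 1) with features z-scored by
training-fold statistics, making accuracy invariant to channel-wise affine
rescaling. Accuracies are averaged over `n_perm` (100; 20 at desk scale)
permutations. Multiclass control labelings (e.g. 8 response locations)
run all pairwise binary decodings and average them (one-vs-one), keeping
chance at 50%.

The SVM is solved by a compact SMO (maximal-violating-pair) dual solver
implemented in C++ inside the package, with the fold loops and temporal
generalization in C++ as well; at pseudo-trial sizes (≤ 20 samples) each
fit costs microseconds, which is what makes permutation-averaged
sliding-window decoding and its calibration studies tractable on one CPU.
The solver is cross-checked against libsvm (via `e1071`) in the test
suite: dual objectives and decision values agree to solver tolerance.
`temporal_generalization()` reuses each fold's fitted readout across all
testing times within a permutation, so its diagonal equals the 1-d curve
*exactly* under a shared seed — a property the tests assert.

Two statistical properties of this scheme are worth flagging. First,
pseudo-trial CV on a *fixed* small trial sample has high per-dataset
variance: all permutations resample the same trials, so a single 60-trial
dataset can decode a few points above or below 50% at every time point.
Grand averages over independent datasets are calibrated at chance (the
acceptance script measures this). Second, the cross-validated accuracy at
chance has a slight pessimistic bias (below 50% by under a point), a known
small-sample CV effect.

## 6. Group inference

`cluster_permutation_1d()` computes pointwise one-sample t statistics
against chance, thresholds at the right-tail critical t for
`alpha_cluster` (0.05), takes maximal contiguous suprathreshold runs, and
compares each run's size to the Monte Carlo null of the maximal cluster
size over sign flips of the subject-wise deviations (1,000 permutations at
full scale; p = (b+1)/(m+1)). Cluster *size* is the primary statistic;
mass (summed t) is offered as an option and is the better-behaved choice
when effects saturate the epoch, since size ties at the epoch length.
`cluster_permutation_2d()` is the same procedure with 4-connected
components for temporal generalization matrices. Ties across subjects
(quantised accuracies) would make the t statistic 0/0; the variance is
clamped so a tie at chance maps to t = 0 and a tie away from chance to a
large finite t, consistently for observed and permuted data.

`brain_behavior_correlation()` computes, per subject and time point, the
Spearman correlation across fake variants between behavioral accuracy and
real-vs-variant decoding accuracy, then runs the 1-d cluster test on the
correlation curves against zero. The across-variant (within-subject)
reading of the correlation is implemented; correlating across subjects
instead would be the alternative reading. `behavior_tests()` reports the
signed-rank V, a tie-corrected normal-approximation Z, an exact p from the
signed-rank null when there are no ties (n ≤ 50), and r = Z/√n as the
effect size (the conventional d for signed-rank contrasts is not uniquely
defined, so r is reported as primary).

## 7. Problem sizes and calibration studies

Desk-scale defaults keep every study on one CPU in minutes: 6 simulated
subjects × 60 trials, 20 subaverage permutations, 200-permutation cluster
nulls, and a 16-channel montage subset with the full 290-point grid for
chance-calibration runs (channel count affects runtime, not the chance
level). The familywise-error study uses 200 independent null runs of 20
subjects × 290 points with 200 permutations each. Effect-recovery tests
run 6 subjects × 240 trials with 5 µV effects on the full montage — the
regime where cluster-size inference at these sizes has power; the late
(perioffset) window abuts the epoch end, which caps its maximal run length
and makes it the power-limiting case. The full-scale study conditions
(600 trials, 20 subjects, 100 permutations, 1,000-permutation nulls) are
the package defaults wherever a paper-scale value exists.

## 8. Known limitations

Monaural only: no interaural time/level/correlation cues, and no
room-geometry simulation — IR realism lives entirely in subband decay
statistics. The EEG simulator is not a biophysical forward model; effects
are additive patterns in sensor space. Subband RT60 estimation is limited
by filter overlap (Section 1) and low-frequency degrees of freedom. A
common montage per run is required; heterogeneous montages across subjects
are not supported.
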