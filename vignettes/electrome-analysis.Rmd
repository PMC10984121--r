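---
title: "Simulating and analysing plant electromes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing plant electromes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(electromer)
```

## The problem

The *electrome* is the totality of an organism's bioelectrical activity
over time. In plants it is commonly sampled as an electrophytogram: the
voltage difference ΔV (mV) between two electrodes inserted in the stem,
recorded for hours at tens of hertz. Electromes are sensitive to the
plant's environment — osmotic stress in particular changes the rate and
amplitude of spike-like transients (action-potential- and
variation-potential-like waves), the shape of the voltage distribution,
the spectral slope and the signal's regularity — so the recording carries
a classifiable signature of the stimulus.

`electromer` implements the full analysis chain for this kind of data:
a seeded simulator of stimulus-specific recordings, a nine-statistic
characterization ledger, an interval-arithmetic feature reduction, a
multi-classifier evaluation harness, and paired before/after statistics.
Because raw recordings of this kind are rarely deposited, the simulator is
a first-class, tested component: it provides the controlled ground truth
against which every estimator in the package is validated.

## The signal model

A synthetic electrophytogram is the sum of four components, each drawn
with its own seed derived deterministically from the series' master seed:

* **Baseline**: colored noise with power spectrum ∝ 1/f^β, produced by
  spectral synthesis (Fourier amplitudes shaped as f^(−β/2), uniform
  random phases, inverse FFT), rescaled exactly to the target standard
  deviation σ. Spectral synthesis is used precisely because the
  β-estimator must be able to recover the generating exponent without
  model mismatch.
* **Spikes**: a homogeneous Poisson train of waveform templates.
  Absolute amplitudes follow a Pareto law P(|A|) ∝ |A|^(−µ) truncated to
  [A_min, A_max] (default 0.05–10 mV), matching the "larger is rarer"
  phenomenology of scale-free electromes; polarity is Bernoulli. Two
  templates are provided: a fast biphasic AP-like pulse (default 4 s,
  damped sine) and a slow monophasic VP-like gamma-shaped wave
  (default 60 s). The field describes these waves qualitatively but
  publishes no templates, so both are explicit parameterized choices.
* **Burst**: an optional window (for the salt treatment: the first
  30 min after stimulation) in which the event rate is multiplied by a
  configurable factor ≥ 1, implemented as a second, independent Poisson
  train at rate (multiplier − 1) × base confined to the window. A
  piecewise-constant-rate Poisson process is the simplest mechanism
  consistent with the described onset burst.
* **Slow waves**: an optional count of single-period, Hann-tapered sine
  waves (default period 600 s, amplitude 1.5 mV) at uniform random
  onsets, emulating the long-period waves seen after salt shock.

The acquisition chain of the emulated recorder (ECG-configured, 62.5 Hz
sampling) nominally band-passes 0.5–100 Hz; at a 31.25 Hz Nyquist
frequency only the high-pass half has a digital counterpart. The package
therefore applies a zero-phase (forward–backward) second-order
Butterworth 0.5 Hz high-pass and treats the low-pass as an analog
pre-digitization stage that is not modelled. Narrow instrument tones at
2.5/5/7.5 Hz, visible in real reference-electrode spectra, can be
injected rather than filtered; reference-electrode series produced by
`realize_series()` carry them by default. Note that a faithful 0.5 Hz
high-pass strongly attenuates the slow-wave component (periods of
minutes); pass `highpass_hz = NULL` to inspect it unfiltered. The mean is
removed before filtering — the high-pass eliminates DC regardless, and
doing it first avoids a large edge transient from uninitialized filter
states.

### Default treatment profiles

The four shipped profiles (`default_profiles()`, stored as
`inst/extdata/profiles.yaml`) encode the qualitative study conditions:
pre-stimulus baselines oscillate within roughly ±0.05 mV (σ ≈ 0.02 mV
baseline, ≥ 95 % of samples inside the band) with rare spikes below
±0.5 mV; the osmotic treatments (PEG, NaCl) gain frequent high-amplitude
spikes reaching the 5–10 mV range; NaCl additionally gets the onset burst
(rate multiplier 6 over the first 1800 s) and four slow waves. **Event
rates are order-of-magnitude choices**: the literature reports amplitude
bands, burst windows and qualitative frequency increases but no
quantitative spike rates, so the defaults (6/h quiet, 40–60/h stressed)
were chosen once as plausible values and are not calibrated to any real
table of results. The profiles were chosen so that qualitative orderings
hold — notably that post-PEG/NaCl approximate entropy falls below its
pre-stimulus level, which emerges naturally: large spikes dominate the
series' standard deviation, the ApEn tolerance r = 0.2·SD grows with it,
and the baseline looks regular at that scale.

### The session manifest

The default `session_design()` reproduces the emulated study: water
30 plants / 10 sessions, nutrient solution 21 / 7, PEG 54 / 18, NaCl
39 / 13; each plant yields a before and an after series (288 electrome
series), each session a pair of dead-stem reference-electrode series
(96), at 450,000 samples per series (2 h × 62.5 Hz) — 172,800,000 points
in total. `generate_manifest()` only enumerates; series are synthesized
on demand, and any single row can be regenerated in isolation because
every series' seed derives from (master seed, experiment, plant, phase).

## The characterization ledger

Nine statistics per series, with these conventions:

* **Mean voltage variation** — the mean of |ΔV|. After a 0.5 Hz
  high-pass every series is near zero-mean, so the signed mean is ≈ 0
  and uninformative; reported per-series magnitudes (~10⁻³ mV) are only
  reproduced by the absolute mean. `signed = TRUE` restores the signed
  version.
* **Skewness / kurtosis** — classical moment estimators (e1071 type 1);
  kurtosis is *excess* (normal → 0). Published kurtosis values for
  stressed electromes are in the hundreds to thousands, so the ±3
  convention difference is immaterial.
* **PDF exponent µ** — |ΔV| is binned into 50 log-spaced bins and log
  density is regressed on log amplitude over a tail range (default:
  above the 90th percentile), mirroring the regression-style exponent
  fits used in prior electrome work; a truncated-Pareto ML fit is
  available (`method = "ml"`). Fits with < 10 tail samples or < 5
  nonempty bins are *flagged*, not raised as errors.
* **Autocorrelation** — the first lag at which the sample ACF drops
  below 1/e, in seconds. Published "AC" values for such data have
  unstated units; the 1/e decay lag is a documented stand-in with a
  closed-form oracle (AR(1) with coefficient φ decorrelates at −1/ln φ
  samples), right-censored at `max_lag` (default 60 s) when the ACF
  never crosses.
* **PSD exponent β** — Welch averaged periodogram (8 segments, 50 %
  overlap, Hann window, per-segment mean detrend), ordinary least
  squares of log power on log frequency over 0.05–10 Hz. The band skirts
  instrument tones at the top; note that on *filtered* series the
  0.05–0.5 Hz shoulder of the high-pass flattens the spectrum and biases
  β low — the estimator is validated on unfiltered colored noise, where
  it recovers β ∈ {0, 1, 2} to within ±0.15 (mean of 20 seeds at
  N = 65,536).
* **ApEn(m, r)** — the original Pincus definition (Φᵐ − Φᵐ⁺¹, Chebyshev
  distance, self-matches included), m = 2, r = 0.2·SD — the
  field-standard parameters, since none are published for this data.
  The kernel is compiled (O(N²) time, O(N) memory); series longer than
  `max_points = 10,000` are decimated by keeping every k-th sample
  (450,000 → every 45th), with r always computed from the undecimated
  series. ApEn at full N = 450,000 would take hours per series;
  correctness of the fast path is guarded by an independent brute-force
  oracle (explicit embedding + `dist(method = "maximum")`) at small N.
* **FFT** — the one-sided amplitude spectrum (a sinusoid of amplitude A
  reads as magnitude A), checked against the discrete Parseval relation
  and the Wiener–Khinchin identity in the tests.
* **Multiscale ApEn** — coarse-graining by non-overlapping means of s
  consecutive samples, s = 1…50, with r *fixed from the original series*
  so that changes across scales reflect the coarse-graining rather than
  a moving tolerance; scale 1 is exactly the plain ApEn.

`feature_ledger()` computes all nine, never aborts, and flags whatever a
degenerate series makes undefined (e.g. moments of a constant signal).

## Interval-arithmetic reduction and classification

Each series is cut into non-overlapping windows of 30,000 samples
(trailing partial window dropped) and each window summarized by
[min, mean, max] — 15 triplets / 45 scalars per standard series. The
literature defines the triplet once as [min, *med*, max] and twice as
using the *average*; the package follows the majority reading (mean) and
offers `center = "median"`. Alternative window sizes (1,000 / 5,000 /
15,000) are plain parameters.

The harness evaluates six classifiers — KNN (k = 5, standardized,
k shrinks to the training-set size when needed), CART decision tree
(unlimited depth: minsplit 2, minbucket 1, cp 0), random forest
(100 trees), Gaussian naive Bayes, RBF SVM (standardized), and a
single-hidden-layer ANN (32 units, decay 0.01, 300 iterations,
standardized) — over training fractions 0.1–0.9 with 20 repetitions
each. Hyperparameters are unpublished for the emulated protocol; these
are fixed, documented defaults. Splits are *stratified* by class
(unstratified draws can lose a class entirely at fraction 0.1); a split
that still loses a class is logged and redrawn. Every repetition's split
derives its seed from (master seed, classifier, fraction, repetition),
so any cell of the learning curve is reconstructible in isolation.
Confusion matrices are row-normalized (row = true class, so the diagonal
reads as per-class recall — the natural reading of "recognized X % of
the before-class") and pooled over the repetitions at the chosen
fraction. Per-repetition accuracies feed the two-sided paired Wilcoxon
signed-rank comparison; all-zero paired differences are reported as "no
difference detectable" rather than a p-value.

## Paired before/after statistics

`paired_compare()` assesses normality of the paired differences with
Shapiro–Wilk at α = 0.05 (no routing test is published for the emulated
protocol; this is the conventional choice, and both the check and α are
configurable), then runs the paired t-test if normality is not rejected
and the Wilcoxon signed-rank test otherwise, two-sided in both cases.
Constant nonzero differences cannot pass a normality check and route to
Wilcoxon; identical phases short-circuit to a degenerate "none" outcome.
No multiple-testing correction is applied across ledger variables,
matching common practice in this literature. Calibration: under the null
with automatic routing, the type-I error at α = 0.05 stays within
[0.03, 0.07] for both normally distributed and heavy-tailed (Cauchy)
differences (2,000 replicates each in the acceptance tests).

## Numerical choices and degenerate inputs

* Constant series: ApEn is exactly 0 (every template matches); moments
  and ACF are flagged as undefined; CV of a constant is 0 %, CV of
  zero-mean data is undefined (NA with a warning).
* The colored-noise generator forces the Nyquist bin real and rescales
  to σ exactly, so `sd(x) == sigma` to float precision.
* Filters: cutoffs must lie strictly below Nyquist; filtering is linear
  and zero-phase by construction (forward–backward pass).
* Series files round-trip at 12 significant digits; readers reject
  non-finite values with the offending line number.
* `derive_seed()` folds labels into a 31-bit linear-congruential hash,
  keeping every derived seed a valid R integer.

## What the simulations do and do not show

The synthetic generator reproduces the *statistical structure* described
for this class of recordings — amplitude bands, spectral exponents,
scale-free spike amplitudes, burst timing, entropy orderings — not any
real plant's electrome. Passing tests demonstrate that the estimators
recover known ground truth and that the harness is calibrated (chance
accuracy on shuffled labels, perfect accuracy on separable classes);
they do not certify classification accuracy on real recordings, where
electrode drift, inter-plant variability and non-stationarity are richer
than the model. Real-data values from the emulated study (per-treatment
feature tables, per-figure classifier accuracies) are explicitly not
reproduction targets, since those raw recordings were never deposited.

Problem sizes used in the test suite are chosen for a desk-scale run:
entropy oracles at N ≤ 500, exponent recovery at N = 65,536 (spectral)
and N = 10⁵ (tail fit), harness checks on 120–400 feature vectors, and
an end-to-end pipeline on a miniature design (2 experiments × 4 plants ×
3,000 samples). The defaults of every function remain the full-scale
study values (450,000 samples, 50 scales, 20 repetitions).

## Session info

```{r}
sessionInfo()
```
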