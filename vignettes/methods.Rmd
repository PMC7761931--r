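---
title: "Methods: source-network EEG features and severity-subtype classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: source-network EEG features and severity-subtype classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srcnet)
```

This vignette is the package's own account of the models and procedures it
implements, the choices that were genuinely open, and what the synthetic
validation does — and does not — establish about real data.

## The analysis model

The pipeline treats a subject as a set of node-level time series (cortical
source reconstructions in the intended application; abstract labelled nodes
here) and produces one feature vector per subject:

* **Epoching and artifact control.** Continuous recordings are cut into
  non-overlapping 2-s epochs. An epoch is removed if any sample at any node
  strictly exceeds ±100 µV, or if its theta (4–8 Hz) to alpha (8–12 Hz)
  power ratio strictly exceeds 1. Powers are integrated from the raw
  periodogram by the rectangle rule over bins strictly inside the band
  edges and averaged over nodes, giving one scalar ratio per epoch. After
  rejection, 30 epochs are drawn uniformly without replacement.
* **Band decomposition.** Eleven bands: delta 1–4, theta 4–8, alpha 8–12,
  alpha1 8–10, alpha2 10–12, beta 12–30, beta1 12–18, beta2 18–22,
  beta3 22–30, beta4 18–30, gamma 30–55 Hz.
* **Connectivity.** Instantaneous phase from the analytic signal
  (frequency-domain construction); the phase-locking value
  `PLV(x, y) = |mean_t exp(i(φ_x − φ_y))|` for every unordered node pair.
  PLV is computed within each epoch and averaged across epochs; 10% of
  samples at each epoch edge are discarded first.
* **Graph features.** With PLV weights `W` (diagonal excluded, no
  thresholding): local clustering coefficient per node by the
  geometric-mean triangle formulation on weights normalised by the matrix
  maximum, its mean over nodes (global CC), and the characteristic path
  length — the mean over node pairs of shortest-path distances on edge
  lengths `1/w`. Per band this gives `n_nodes + 2` features; with 148 nodes
  and 11 bands, 1650 features.
* **Severity subtyping.** PANSS items (30 items, each 1–7) are summed into
  the standard subscales and the five-factor scores — positive (P1, P3, P5,
  P6), negative (N1, N2, N3, N4, N6, G7, G16), cognitive/disorganization
  (P2, N5, G9, G10, G11, G13, G15), excitement (P4, P7, G8, G12, G14),
  depression/anxiety (G2, G3, G4, G6). A cohort is split at the median of a
  chosen score; the default rule labels a subject *high* iff its score
  strictly exceeds the median.
* **Classification.** Two-class linear discriminant from class means and
  pooled within-class covariance, ridge-stabilised by `1e-6 × trace(S)` on
  the diagonal so collinear features never abort a fit; class priors are
  empirical frequencies. Sequential forward selection (SFS) adds the
  feature maximising mean stratified k-fold CV accuracy on the candidate
  set, stops at no improvement or 30 features, and breaks ties to the
  lowest feature index. Performance is reported from 10 repetitions of
  stratified 10-fold CV: accuracy, sensitivity (recall of the designated
  positive class), specificity, and a fold-averaged ROC curve (vertical
  averaging on a fixed false-positive grid).
* **Significance.** A mean accuracy is compared against the binomial
  threshold `St_α = binoinv(1 − α, n, 1/c) × 100 / n`, the smallest
  accuracy whose correct-count could not arise from chance (probability
  `1/c` per sample) with probability ≥ `1 − α`. For two classes this gives
  55.46% at n = 238 and 57.14% at n = 119 (α = 0.05), against a theoretical
  chance level of 100/c = 50%.

## Where selection enters the estimate: `paper` vs `nested`

Whether feature selection is refit inside every cross-validation fold is
the single most consequential design choice in this kind of pipeline. Both
modes are implemented in `run_pair()`:

* `mode = "paper"` (default): SFS runs once on the complete data set; the
  selected set is then assessed by repeated CV. This replicates the common
  study design, but the selection step has seen the evaluation data, so the
  estimate is optimistic.
* `mode = "nested"`: SFS is re-run inside every training fold and the
  held-out fold is scored with that fold's own selection. This is the
  statistically sound estimate.

The acceptance suite quantifies the difference: on pure-noise features with
permuted labels (n = 50, 30 features, 50 runs at reduced CV scale —
5-fold × 2 repeats, SFS capped at 10), nested selection exceeded the 62%
binomial threshold in 1/50 runs (consistent with α = 0.05), while
non-nested selection exceeded it in 42/50 runs with a mean "accuracy" of
about 67% — on data containing no signal at all. Conclusions about
above-chance decoding should rest on nested mode or on the binomial
threshold applied with that bias in mind.

## The synthetic cohort generator

Real clinical EEG cannot ship with the package, so validation runs on
synthetic cohorts with known ground truth. The generator emulates the
working conditions of the pipeline: 2-s epochs at 1000 Hz, 30 epochs per
subject, ~148 nodes, band-limited oscillations, occasional high-amplitude
artifacts, and two cohorts differing in coupling topology and PANSS
severities.

**Coupling model.** Each coupled edge (i, j) in a band contributes to both
nodes a shared carrier `cos(2πf₀t + φ(t))`; node j's copy is offset by a
jitter process `ε(t)`. The base phase φ is a Brownian track (diffusion 10
rad²/s by default) — the classic finite-linewidth oscillator — so distinct
edges and uncoupled nodes decorrelate within ~0.1 s. The jitter is a
*continuous stationary Gaussian process*: white noise convolved with a
Gaussian kernel of correlation time 0.1 s, normalised so the marginal is
exactly N(0, σ²). For any stationary Gaussian jitter the expected PLV is
the wrapped-normal resultant

> E[PLV] = exp(−σ²/2),

independent of the base-phase dynamics. This closed form is what makes the
generator a usable oracle. A piecewise-constant (block-wise) jitter would
give the same expectation in exact phases, but its discontinuities bias the
analytic-signal phase estimate near every jump; the continuous process was
chosen to keep the estimator unbiased at the accuracy the calibration tests
require.

**Finite-sample floors.** Two floors matter when interpreting PLV values
from the generator. First, over a finite window the magnitude of a mean
phasor is upward-biased: `E|mean| ≈ sqrt(m² + (1 − m²)·τ/T)` for expected
resultant `m`, correlation time τ and window length T. Per-epoch averaging
over 2-s epochs therefore sits above `exp(−σ²/2)` (Monte-Carlo oracle at
σ = 1: 0.670 ± 0.03 versus 0.607), while concatenating epochs before the
PLV recovers the analytic value; both modes are available in
`plv_matrix()`, with per-epoch averaging the default because epochs are the
unit of artifact control. Second, uncoupled node pairs have a nonzero PLV
floor (~0.3–0.45 at 2-s epochs with the default Brownian base phase); group
contrasts are therefore encoded as differences relative to that floor, not
against zero.

**Other generator choices.** Oscillation amplitude 10 µV per band component
with 5 µV additive white noise keeps clean epochs well inside the ±100 µV
limit while making in-band noise negligible for phase estimation. Artifacts
are injected as 50-sample square pulses of 150 µV in a random node of a
randomly chosen epoch — directly exercising the amplitude rule. PANSS items
are drawn from a normal distribution (baseline mean 3, SD 1.5), shifted per
item by a configurable group effect, rounded and clipped to 1–7 — the
simplest ordinal model with a controllable group shift. All randomness
derives from one master seed through documented integer substreams
(`derive_seed()`), so cohorts are bit-reproducible.

**What passing tests do not show.** The generator is a test harness, not a
biophysical model: it has no volume conduction, no 1/f background, no
non-stationarity across epochs beyond phase dynamics, and no realistic
artifact morphology. Passing calibration and effect-recovery tests
establishes that the *pipeline* measures what it claims on signals with
known structure — not that any particular clinical effect size is
detectable in real recordings.

## Numerical choices

* **Band-pass filter.** Zero-phase 4th-order Butterworth response, applied
  as the squared magnitude response (one forward plus one backward pass) in
  the frequency domain after an even (mirror) extension of each epoch. This
  is linear, exactly phase-free, vectorised across nodes and epochs, and
  meets the stated contracts: in-band gain within [0.9, 1.1] and ≥ 20 dB
  attenuation one octave outside the band edges.
* **Periodogram.** Raw (untapered) one-sided periodogram scaled as density
  per Hz; summing `power × Δf` recovers the mean squared amplitude
  (Parseval), which the tests assert to 1e-10.
* **Strictness and ties.** "Exceeding ±100 µV" is strict (a sample exactly
  at 100 µV is kept). The theta/alpha rule is strict with a 1e-9 relative
  slack so a ratio numerically equal to 1 is kept. An epoch with vanishing
  alpha *and* theta power has an undefined ratio and is removed with a
  warning; vanishing alpha with real theta power gives an infinite ratio
  and is removed by the rule itself. SFS ties break to the lowest feature
  index. Median-split assigns median-valued subjects to *low* by default
  (`rule = "ge"` flips this); the choice is exposed because group sizes at
  a median cannot be reconstructed from the split rule alone.
* **Degenerate inputs.** All-zero weight matrices yield zero clustering
  with a warning; disconnected graphs average path length over reachable
  pairs with a warning; single-node feature assembly, constant signals in
  phase estimation, and single-class classification all error early with
  specific messages.
* **Path length "sum" mode.** The characteristic path length is reported as
  the mean over unordered pairs (the standard definition, comparable across
  network sizes); `mode = "sum"` returns the literal sum for users who want
  the unnormalised total.
* **Inverse binomial CDF.** `binom_inv()` delegates to `qbinom` (smallest k
  with CDF ≥ q); the tests verify it against explicit summation of the
  binomial mass function for n up to 500.

## Problem sizes used in the validation suite

The acceptance checks run at scales chosen to exercise the full pipeline
while remaining desk-reproducible: PLV calibration uses 24 replicates of
30-s coupled pairs per jitter level (σ ∈ {0, 0.5, 1, 2}), asserting
agreement with exp(−σ²/2) within 3 Monte-Carlo standard errors;
graph metrics are checked against brute-force triangle enumeration and
Floyd–Warshall shortest paths on 100 random 8-node graphs to 1e-10; effect
recovery uses 20 independent 2×20-subject cohorts (20 nodes, 2 bands, six
edges at σ = 0.2 vs 2.5) and requires the group contrast to exceed its
binomial threshold in at least 19; the null calibration described above
uses 50 permutation runs. The 148-node × 11-band dimensionality check runs
on a single synthetic subject.

## Known limitations

* `mode = "paper"` is the default for comparability with the replicated
  study design, despite its documented optimism; nested mode is the
  estimate to trust.
* Per-epoch PLV averaging carries the finite-sample floor quantified above;
  comparisons should stay within one epoch-length/averaging convention.
* The weighted clustering coefficient normalises by the global weight
  maximum, so it is scale-free but *not* invariant to the PLV floor of a
  particular generator configuration.
* The pipeline starts at node-level time series: source localisation,
  forward modelling and sensor-space artifact correction are upstream of
  this package and out of its scope.
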