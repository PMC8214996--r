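---
title: "Methods: wavelet-packet staging of photoacoustic spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet-packet staging of photoacoustic spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pastage)
```

## The analysis in one paragraph

A photoacoustic trace is a 1-D time series of ultrasonic pressure sampled
at 2.6 MHz for 2 ms (5200 samples). The pipeline standardizes each trace
(detrend, baseline, optional background, max-absolute normalization), keeps
the 0.27–0.6 ms region of interest where staged tissue differs most,
expands the labelled set 10-fold by amplitude rescaling, summarizes every
trace by the 215 coefficients of the level-2 approximation subband (AA2) of
a Daubechies-6 wavelet packet decomposition, ranks those coefficients by
greedy minimal-redundancy maximal-relevance (mRMR) selection, and evaluates
one-vs-one multi-class SVMs on the top 10 under repeated stratified 80/20
hold-out. Every stage is a tibble-in/tibble-out verb, so the whole chain
composes with the pipe.

## The synthetic generator: what it emulates, and what it does not

Raw recordings of this kind are typically available only on request, so the
package is driven by a seeded generator that reproduces the *statistical
design* of such an experiment: 5 ordered groups (day 0 control to day 20),
5 tissues per group, 4 probe positions per tissue, 5 replicate traces per
position — 500 originals, 100 per group.

Each group's template is a mixture of three transient components, each a
damped sinusoid with a smooth quadratic onset ramp
\((t-t_0)^2 e^{-\gamma (t-t_0)} \sin(2\pi f (t-t_0) + \phi)\), normalized
to unit peak envelope. The smooth ramp is a deliberate choice: a hard
onset gate has \(1/f^2\) spectral energy tails that would push roughly 2%
of the energy above the AA2 band edge at these dampings (a Lorentzian-tail
calculation), contradicting the band-limitation that makes AA2 the feature
source; physically it corresponds to a finite acoustic rise time.
Defaults place component frequencies at 45–140 kHz — well below both the
650 kHz quarter-sampling bound and the ~325 kHz AA2 band edge — with
dampings of 1.5–4 × 10⁴ s⁻¹ so transients decay inside the window, and
onsets at 0.30–0.45 ms inside the ROI.

Groups differ in two ways, both tunable in `class_templates()`:

* **Amplitude** (`amplitudes`, a.u., default `seq(1, 2.4, length.out = 5)`),
  strictly increasing with day index to mimic the stronger photoacoustic
  response of advancing tumors. Because normalization rescales every trace
  to unit peak, amplitude acts on the *signal-to-noise ratio* of the
  normalized trace rather than on its gross scale.
* **Shape** (`shape_drift`, default 1): per-day increments in component
  frequency (+15 kHz and +8 kHz per day for the two leading components),
  onset (+5 µs and +8 µs per day) and mixing weight (+0.08 per day).
  `shape_drift = 0` produces shape-identical classes that differ only
  through the amplitude dial — the configuration used to probe how spacing
  drives separability.

Hierarchical realism comes from log-normal multiplicative random effects at
the tissue (`tissue_effect_sd = 0.08`) and position (`position_effect_sd =
0.05`) levels, shared by all traces nested under them; per-trace
randomness is white Gaussian noise (`noise_sd = 0.01` a.u.), a random
quadratic baseline (`drift_sd = 0.02` per coefficient) and a small onset
jitter (1 µs). These values were fixed once as plausible for
preamplified PZT recordings with ~100:1 peak signal-to-noise; they are not
fits to any published trace, because no quantitative morphology of such
traces is published — only the study design is. Consequently, passing
tests show that the *pipeline* behaves correctly on data with this
structure; they cannot certify classification accuracy on real recordings,
whose within-group heterogeneity is unknown.

One master seed fans out via a fixed affine hash (`substream_seed`) into
per-tissue, per-position and per-trace substreams indexed by a counter
scheme, so any subset of the dataset can be regenerated independently and
`generate_spectra()` is a pure function of (design, templates, seed).

## Pre-processing decisions

The four standardization steps are named but not specified by estimator in
the staging literature, so the estimators here are the conventional ones,
all config-exposed:

* detrend = least-squares straight line over sample index;
* baseline = least-squares polynomial, order 2 by default (order 0 is mean
  removal);
* background subtraction defaults to off — the synthetic design has no
  blank cuvette trace — but accepts any user-supplied trace;
* normalization = division by the maximum absolute amplitude, which
  preserves waveform shape and sign and is idempotent.

Order is fixed: detrend → baseline → background → normalize → ROI.
Normalizing *before* windowing means the ROI inherits the full-record
scale; the alternative order would renormalize within the window and
slightly alter relative amplitudes. ROI bounds use 0-based half-open
indexing `[round(start·rate), round(end·rate))` with round-half-away-from-
zero, which makes the 0.27–0.6 ms window exactly 858 samples at 2.6 MHz on
every platform.

## Augmentation

`pa_augment()` returns originals plus one copy per factor of the grid 0.5,
1.0, …, 4.5. The grid deliberately keeps factor 1.0 even though that copy
equals its original up to provenance, because the published grid is printed
that way; users who want nine *distinct* variants can pass their own
`augment_plan()`. Augmented traces are not re-normalized — re-normalizing
would cancel the scale and void the augmentation. Augmentation happens
after pre-processing/ROI, never before.

A consequence worth knowing: under row-wise train/test splitting, rescaled
copies of one original can straddle the split. Standardized AA2 features of
such siblings are nearly collinear, so a classifier can "recognize" a test
row from its training siblings. The package exposes both the faithful
row-wise policy (`policy = "paper"`, the default) and a `"grouped"` policy
that keeps all rows of one origin on one side; with shape-identical
templates the gap between the two is large (the grouped estimate is the
honest generalization estimate), and the test suite demonstrates it.

## The wavelet packet stage

The level-2 decomposition uses the orthonormal db6 filter pair (12 taps;
highpass by the quadrature-mirror relation) in a periodized circular
filter bank, natural (filter-bank) node ordering, so AA2 ≡ node (2,0) is
the twice-lowpassed band covering 0 to rate/8.

Boundary handling is the one place where standard conventions disagree,
and it matters at this record length: 858 → 429 (odd) → 215. Classic
odd-length periodization duplicates the last sample, which is not an
isometry, so subband energies would not sum to the signal energy to high
precision. This package instead zero-pads an odd-length parent by one
sample and applies the even-length orthonormal circular transform. Child
lengths still follow the `ceiling(n/2)` rule, energy is conserved exactly
(the pad contributes none), and reconstruction is exact because inversion
provably restores the pad as zero before it is dropped. The test suite
verifies energy conservation and reconstruction to 1e-9 at lengths
64/215/858, nodewise linearity, agreement with a brute-force circular
convolution oracle at length 16, and level-2 equipartition (~1/4 per node)
for white noise.

`energy_distribution()` errors on an all-zero signal (fractions undefined)
rather than returning NaNs.

## mRMR decisions

Mutual information is estimated from the empirical joint frequency table
after equal-frequency (quantile) binning of continuous features into
⌈√n⌉ bins, capped at 256. Quantile binning is invariant to monotone
rescaling — important when 9 of every 10 rows are scaled copies. The
greedy criterion is the difference ("MID") scheme,
\(I(x;y) - \frac{1}{|S|}\sum_{s \in S} I(x;s)\): it is the common default
and has no division-by-zero issue at zero redundancy; the quotient scheme
is available via `scheme = "miq"`. Scores are the raw criterion values at
selection — the first is the plain relevance in nats, later ones may go
negative once redundancy dominates; they are comparable in ordering
semantics only, not in scale, across estimators. Ties break towards the
lower coefficient index so rankings are reproducible.

## SVM decisions

Kernels: RBF, polynomial, linear. Hyperparameters are not published for
this analysis, so conventional defaults are used and config-exposed:
C = 1; γ = 1/(d · var) of the standardized training features (≈ 1/d);
polynomial degree 3, offset 1. Features are standardized with center and
scale learned from training rows only. Multi-class reduction is one-vs-one
with vote counting (libsvm via `e1071`), matching the binary
decision-function formulation
\(\hat f(x) = \sum_j \alpha_j y_j G(x, x_j) + b\), which
`svm_binary_model()`/`decision_score()` implement directly and the tests
cross-check against libsvm's decision values.

Evaluation reports a 5×5 confusion matrix (rows = truth), per-class
sensitivity, one-vs-rest specificity and trace/total accuracy, all in
percent; a class absent from a test partition yields an explicit NA plus a
warning, never a silent drop. `repeated_holdout()` reuses identical split
seeds across kernels so kernel comparisons are paired, and nominates the
highest-accuracy repeat per kernel (ties towards the earlier seed).

## Problem sizes and determinism

The shipped tests run the full default design (500 originals → 5000 rows →
5000×215 features → 5000×10 matrix) for the count and recovery checks, a
2×2×2 design for the slower stochastic properties (amplitude-spacing dial,
split-policy comparison, each over 5 seeds), and small constructed tables
for every hand-verifiable computation. The parameter-recovery check runs
the complete pipeline over 5 master seeds with 10 polynomial-kernel
repeats each, against a label-permuted control that must stay near the 20%
chance level. All randomness flows from explicit seeds; reruns are
bit-identical, and `run_pipeline()` records every derived seed in its
manifest.

## Known limitations

* The generator captures the design, band-limitation and nesting of the
  study, not the physics (no optical absorption, Grüneisen or acoustic
  propagation model) and not real biological heterogeneity; accuracies on
  synthetic data say nothing quantitative about accuracies on recordings.
* The mRMR importance scale depends on the MI estimator; only the ordering
  is meaningful.
* The default row-wise split policy reproduces the published protocol,
  including its augmentation leakage; for honest generalization estimates
  use `policy = "grouped"`.
* Wavelets are limited to the Daubechies family members shipped
  (haar/db2/db4/db6); level is fixed by config, with no best-basis search.
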