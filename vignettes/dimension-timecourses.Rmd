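---
title: "Decoding dimension timecourses: models, statistics, and design choices"
author: "dimtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding dimension timecourses: models, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own methods: the models it
fits, the statistics it computes, what the synthetic-data generator does
and does not emulate, and the choices made where the design was genuinely
open. It states no empirical numbers beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## 1. The estimation problem

The data are epoched multichannel recordings: a tensor of trials ×
sensors × timepoints, each trial showing one object image, plus a
continuous embedding that assigns every stimulus a nonnegative weight on
each of a set of behavior-derived object dimensions. The estimand is, for
each dimension *d*, a timecourse `r_d(t)`: how much information about
dimension *d* the sensor pattern carries at latency *t*.

### Timepoint-wise ridge decoding

At every timepoint a multi-target ridge regression maps the sensor
pattern to all dimension weights simultaneously. Sensors are z-scored
with parameters estimated on the training split only; targets are
centred. The penalty is selected per target over a grid of 100 linearly
spaced values between 1e-6 and 30,000 (`default_alpha_grid()`), by exact
leave-one-out cross-validation computed from a single eigendecomposition
of the training Gram matrix. (An interleaved k-fold option exists,
`cv = "kfold"`; leave-one-out is the default because it is deterministic,
exact, and costs nothing extra on the eigen path.) Performance is the
Pearson correlation between predicted and true weights over the held-out
trials, per dimension; folds are aggregated by the arithmetic mean.
Tuning per target rather than jointly matches the per-dimension reporting
of the timecourses; a shared penalty is available via `per_target =
FALSE`.

Correlations of a constant prediction (or a constant target) are recorded
as 0: a constant carries no trial-to-trial information, and the
convention keeps downstream aggregation total. Zero-variance sensors are
dropped from the fit (coefficient 0) with a warning.

### Cross-validation schemes

*Within participant*: one fold per session — train on all other sessions,
test on the held-out one (`make_session_folds()`). With the study-scale
design of 12 sessions × 1,854 one-per-concept trials this is 20,394
training and 1,854 test trials per fold.

*Across participants*: for every ordered participant pair (A, B) and every
session, train on A without that session and test on B's held-out session
(`make_across_folds()`). Fold sizes are therefore identical to the within
scheme, making the two directly comparable; the scheme is a stringent
test of whether a dimension's sensor code is shared across heads.

### Encoding models

`encode_sensor_timecourse()` fits the converse regression — embedding →
single sensor response — with the same grid, standardization contract,
and session-wise folds, giving per-sensor correlation timecourses that
localize where dimension information lives.

## 2. Permutation statistics

`permutation_null()` implements a label-permutation null that leaves the
trained models untouched: for each of (by default) 1,000 permutations,
one shuffling index is drawn and applied to the test-label rows
*identically in every fold* (which requires equal test-set sizes), the
per-dimension correlations are recomputed against the shuffled labels,
and fold-averaged. `corrected_threshold()` takes the 99th percentile of
each (dimension, timepoint) cell's null and returns the maximum percentile
across all cells as a single family-wise threshold;
`significance_mask()` marks strict exceedances and records per-dimension
onset latencies.

### A known limitation of this null

The fixed-prediction label-shuffle null is exact for a *single* fold: the
held-out prediction is independent of the test labels under the null, so
the observed correlation is one draw from the permutation distribution
(the suite verifies rank-uniform per-fold p-values). It is **not** exact
for the *fold-averaged* statistic. Session-wise folds share training
data — the session that fold *i* tests on is training data for every
other fold — so under the global null the per-fold correlations contain
pairwise-shared noise-alignment terms (fold *i*'s statistic behaves like
`u_i' Σ_{j≠i} u_j` with `u_j = X_j' y`), which correlates folds by up to
`1/(k−1)` and roughly doubles the variance of the fold average relative
to the shuffle null, whose draws are independent across folds. The
consequence is an anti-conservative corrected threshold: on pure-noise
simulations the family-wise false-positive rate of the mask is far above
the nominal level, and the acceptance suite records this honestly as a
failing calibration check rather than adjusting the procedure. A null
that retrains on shuffled training labels would capture the dependence
but is deliberately out of scope here; users needing strict family-wise
control should treat isolated supra-threshold cells (especially
pre-stimulus ones) with caution or raise the per-cell percentile.

### Model comparison

`compare_models()` tests within-minus-across differences at selected
latencies (default 100–600 ms in 100 ms steps) with paired t-tests,
Bonferroni-corrected by the number of tested latencies, significance at
corrected p < 0.01. Pairing is over dimensions by default (matching
per-dimension reporting; n = number of dimensions); pairing over
participants is available via `pair_over = "participants"`. Tests are
two-sided. Latencies not on the sample grid are mapped to the nearest
sample with a warning.

## 3. Shape analysis

The pipeline order is fixed and tested: boxcar smoothing (default 50 ms;
width rounded to an odd sample count, edges handled by shrinking the
window) → z-scoring each (dimension, participant) series over time so
only shape, not signal-to-noise, enters → averaging across participants →
excluding the `floor(0.05 · n)` dimensions with the fewest significant
timepoints (ties broken by smaller count, then input order; 66 dimensions
→ exactly 3 excluded) → pairwise dynamic time warping → hierarchical
clustering.

DTW here is the classic dynamic program on the timepoint-distance matrix
(absolute differences of the two univariate series), with the symmetric
step set {(1,0), (0,1), (1,1)}, boundary-aligned ends, no step weights
and no warping window — none being motivated, the unconstrained classic
form is used. The dissimilarity is the summed local distance along the
lowest-cost path; identical series give cost 0 on the diagonal. The
dynamic program is implemented in C++ and is verified in the suite
against exhaustive path enumeration on short series.

Clustering uses average linkage (UPGMA) on the precomputed matrix —
standard practice for non-Euclidean dissimilarities, where Ward-type
methods lose their variance interpretation — with flat clusters cut at
0.5 × the maximum observed distance and per-cluster mean series as
prototypes. Both the linkage and the cut factor are arguments.

## 4. The synthetic-data generator

`simulate_epochs()` is a linear forward model: trial *i* with weights
`y` evokes `Σ_d y_d · g_d(t) · m_d` plus i.i.d. Gaussian noise, where
`g_d` is the dimension's temporal kernel and `m_d` its sensor projection,
a convex blend `f_d · M_shared,d + (1−f_d) · M_subj,d` of unit-norm
mixing vectors. Epochs are baseline z-scored per trial and sensor over
the pre-stimulus window (exactly mean 0, SD 1 there; a zero-variance
noiseless baseline is centred only).

Temporal kernels (`temporal_profile()`, `make_profile()`):

* **early** — Gaussian bump, default peak 125 ms, SD 30 ms, optionally
  with an offset bump at stimulus duration + 100 ms (i.e. 600 ms for the
  500 ms default stimulus) at half amplitude;
* **late** — smoothstep rise (onset `peak − width`, default 150 ms) to a
  peak at 300 ms, then slow exponential decay (τ = 150 ms): a sustained
  response whose argmax is still unique at the planted latency — a
  perfectly flat plateau would make the planted peak unrecoverable by
  construction;
* **offset** — the offset bump alone; **mixture** — early bump plus late
  component. All kernels are exactly zero before stimulus onset.

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| participants × sessions × concepts | 2 × 4 × 200 | desk scale: full pipeline in minutes; study-scale counts (4 × 12 × 1,854, 66 dims) live in `full_scale_config()` for bookkeeping only |
| sampling rate | 100 Hz | typical analysis grid for epoched decoding; configurable |
| epoch window | −100..1300 ms | baseline plus the full response including offset effects |
| embedding | \|N(0,1)\| with 50% zero mask | sparse nonnegative continuous weights, the qualitative character of similarity embeddings; the marginal law is otherwise unconstrained |
| noise_sd / amplitudes | 1 / 1 (offset 0.5) | chosen once so planted latencies are recoverable at desk scale (peak r ≈ 0.3–0.5), i.e. a realistic single-trial SNR regime |
| shared fraction | 0.9 early, 0.3 late | reproduces the empirical pattern that early stimulus-driven responses generalize across participants while late ones are idiosyncratic; a modeling choice, not data-derived |

The image-level expansion (`expand_to_images()`, `fit_expansion()`)
emulates augmenting a concept-level embedding to image exemplars: image
weights are concept weights plus clipped Gaussian exemplar perturbation;
features are a fixed random full-column-rank linear map of the image
weights plus noise; one ridge model per dimension (5-fold internal CV,
same grid — the fold scheme at this stage being otherwise unspecified)
predicts weights from features, with no nonnegativity constraint on
predictions, so downstream code accepts negative predicted weights.

What the generator does **not** emulate: 1/f or line noise, sensor
covariance and head geometry, eye/muscle artefacts, trial-order or
adaptation effects, nonlinearity of the neural code. Passing tests
therefore demonstrate correctness of the estimation machinery under a
linear, temporally structured ground truth — not robustness to real
recording artefacts.

## 5. Numerical choices and degenerate inputs

* Ridge path via eigendecomposition of the Gram matrix; eigenvalues
  clamped at 0; leverages clamped below 1 for the leave-one-out formula.
* Correlations with a constant side are 0 (flagged), never NA.
* Baseline z-scoring falls back to centring when the baseline variance is
  exactly 0 (noiseless simulations).
* Identical-series DTW ties are broken toward the diagonal step, so equal
  series yield the diagonal path.
* `exclude_low_snr()` uses `floor`, consistent with 66 × 5% → 3.
* Comparison t-tests with zero-variance differences return p = 1 (all
  differences zero) rather than erroring.
* Fold plans, seeds and configs are digested into a run manifest
  (`run_manifest()`); every pipeline output table carries the manifest
  hash in a `#` comment header, and all stage seeds derive from one root
  seed (`derive_seeds()`).

## 6. Problem sizes used by the tests

The suite and the acceptance script run the generator at desk scale —
hundreds of trials, tens of sensors, 4–10 dimensions, 100 Hz — where one
within-participant decode takes seconds and the full pipeline about a
minute; the calibration study for the permutation null uses 50 pure-noise
replicates of a deliberately small two-session design. These sizes are
the package's validation conditions; nothing in the implementation is
specific to them, and study-scale inputs differ only in cost.
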