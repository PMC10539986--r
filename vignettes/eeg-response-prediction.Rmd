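---
title: "Predicting antidepressant response from resting-state EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting antidepressant response from resting-state EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Response to a first antidepressant trial is essentially unpredictable from
clinical presentation, and each failed trial costs two to three months.
Resting-state EEG is cheap, fast and tolerable, which makes it a practical
candidate biomarker source: if a model built on a modest 32-electrode
montage can predict, before treatment starts, whether a patient with major
depressive disorder will respond to an SSRI, even moderate accuracy is
clinically useful.

`eegresponse` implements such a pipeline end to end: spectral and
complexity feature extraction from eyes-closed resting EEG, reduction to a
fixed 152-dimensional feature vector, k-nearest-neighbour (kNN)
classification under fully nested cross-validation, external-cohort
prediction, and permutation feature importance — plus a synthetic EEG
cohort generator so that every stage is testable without access to
clinical recordings.

## Features

**Relative band power.** Power spectral density is estimated per channel
with Welch's method: 2-second nonoverlapping Hamming-tapered segments,
averaged one-sided periodograms, analysis range 1–50 Hz. Absolute power is
integrated in the five canonical bands — delta 1–4, theta 4–8, alpha 8–13,
beta 13–30, gamma 30–50 Hz (half-open `[low, high)`, gamma closed at 50) —
and divided by total 1–50 Hz power, so each channel contributes five
relative powers that sum to one. The band edges are a package choice;
conventions differ across laboratories, and the edges are configurable via
`spectral_config()`.

**Multiscale sample entropy.** Sample entropy is
$\mathrm{SampEn}(m, r) = -\ln(A/B)$, with $B$ the number of template pairs
of length $m$ within Chebyshev distance $r$ (self-matches excluded) and
$A$ the same count at length $m+1$. Multiscale entropy (MSE) evaluates
SampEn on coarse-grained copies of the signal — nonoverlapping block means
of length $\tau$ — for $\tau = 1 \dots 70$. We use $m = 2$ and
$r = 0.15 \times \mathrm{SD}$, computed per channel per 30-second window
at scale 1 and held fixed across scales of that window (the dominant
convention in the MSE literature; per-scale re-estimation is available via
`mse_config(r_per_scale = TRUE)`). Per-subject curves are the mean over
windows, then averaged within three timescale bands: fine (1–20), medium
(21–35) and coarse (36–70).

Degenerate counts are handled deterministically: $B = 0$ yields `NA`
(undefined), and $A = 0$ with $B > 0$ is capped at $\ln(B+1)$, a finite
stand-in for an unobservably large entropy. Band averages skip undefined
scales and fail loudly only when an entire band is undefined.

The pair counting is implemented in C++ with a sorted sweep over first
template components, so only pairs already matching in one coordinate are
inspected; an independent brute-force oracle in the test suite checks the
counts exactly on series up to length 500, and the white-noise limit
$-\ln(2\Phi(r/\sqrt{2}\sigma) - 1) \approx 2.47$ is verified numerically.

## Feature reduction: 152 dimensions

The 32 electrodes are grouped into 14 regions: five left/right lateral
pairs (frontal, central, temporal, parietal, occipital) and four midline
zones (Fz, Cz, Pz, Oz). Features are averaged within regions, and
asymmetry features are computed by dividing each left-hemisphere region
feature by its right-hemisphere counterpart for the five lateral pairs.
With 8 features per region this gives $14 \times 8 + 5 \times 8 = 152$
values per subject, in a frozen, versioned column order
(`feature_names()`), so a trained model and an external cohort cannot
silently misalign. The electrode-to-region assignment is a package default
(`default_region_map()`) and can be replaced by any `region_map()`;
exact groupings differ between studies and are rarely published in full.

Asymmetry ratios are computed on region-averaged features (not averaged
channel-pair ratios), and a right-side magnitude below $10^{-12}$ raises a
division-guard error: relative powers and entropies are strictly positive
for any physiological signal, so a true zero indicates a degenerate
recording that should fail, not propagate.

## Cleaning

The artifact-rejection stage is deliberately simple and fully automated: a
zero-phase 4th-order Butterworth band-pass (1–50 Hz), then rejection of any
2-second segment in which any channel exceeds a peak-to-peak amplitude
threshold (150 µV default), with a quality error if less than half the
recording survives. Clinical pipelines are usually proprietary and
site-specific; this stage is isolated behind `cleaning_config()` so a
site's own pipeline can be substituted without touching anything
downstream. Everything is deterministic, and a second pass never removes
further segments.

## Classifier and validation

kNN is used deliberately: it has only two hyperparameters that matter
(neighbour count $k$ and the distance metric), makes no distributional
assumptions, and behaves well in low-dimensional biomedical feature
spaces. The default grid is odd $k \in \{1, 3, \dots, 25\}$ (odd values
cannot tie a two-class vote) and
{euclidean, manhattan, correlation} distances; chebyshev is available.
All remaining ties are resolved deterministically: distance ties by lower
training index (indices frozen by subject-id sort), vote ties (even $k$
via configuration) by the single nearest neighbour's label.

**Nested leave-one-out cross-validation** (`nested_loocv()`): for each
held-out subject, standardization parameters (per-feature mean and SD) are
fitted and hyperparameters selected — by inner leave-one-out balanced
accuracy — on the remaining subjects only. No final model exists; each
fold may select different hyperparameters, and the aggregate of held-out
predictions is an unbiased performance estimate. Stratified nested
$k$-fold (`nested_kfold()`) is provided for sensitivity analyses and
collapses exactly to LOOCV at $k = n$.

One inner-loop design choice was genuinely open: whether to re-fit the
standardizer inside every inner split as well. We standardize once per
outer training set and reuse those parameters across the inner splits.
The quantity the validation protects — independence of the held-out outer
subject — is untouched (the no-leakage canary test verifies that an
arbitrarily extreme held-out subject cannot change fold-training
standardization or hyperparameter selection), while the inner search stays
$O(n^2)$ per fold rather than $O(n^3)$.

**External validation** (`train_final()`, `predict_external()`): a single
model is tuned by leave-one-out over the full training cohort,
standardization is fitted on the full training cohort, and the external
cohort is standardized with the *training* parameters before prediction.
Columns are aligned by name against the model manifest; any discrepancy is
an error, not a silent reorder.

**Metrics.** Responder (≥ 50% score reduction from baseline to week 8,
boundary inclusive) is the positive class. Sensitivity, specificity and
balanced accuracy are reported with 95% intervals by both the normal
approximation and the exact Clopper–Pearson method; published reports
rarely state which method was applied to which metric, so both are always
computed and stored. The balanced-accuracy interval uses the normal
approximation with the variance of the mean of two independent
proportions. Reported percentages round half away from zero
(`round_away()`), matching how results tables are conventionally printed.

**Permutation importance** (`permutation_importance()`): each feature
column of the evaluation set is shuffled across subjects, breaking its
label association while preserving its marginal distribution, and the mean
reduction in balanced accuracy over 100 seeded repeats is the importance.
The already-trained model is reused; the baseline is computed once.
Negative reductions are possible for uninformative features and are kept
in the raw output; the rendering table for the conventional four-block
heatmap (power, power asymmetry, MSE, MSE asymmetry) floors them at zero,
since "shuffling helps" carries no usable information.

## The synthetic cohort generator

`generate_cohort()` emulates what the pipeline needs from a resting-state
eyes-closed recording, not the full physiology. Each channel is an
independent mixture of:

* a $1/f^\beta$ Gaussian background (spectral shaping of white noise,
  $\beta = 1$ default) — the dominant shape of resting EEG spectra;
* band-limited oscillations (band-pass-filtered noise, not pure
  sinusoids, so narrow-band power fluctuates across windows as it does in
  real alpha): alpha at 10 Hz (bandwidth 4 Hz, relative amplitude 1) and
  beta at 20 Hz (bandwidth 6, amplitude 0.25) by default;
* a broadband white component with mixing fraction 0.3.

Defaults are 32 standard 10-20 channels, 250 Hz sampling and 120 s
duration — typical clinical acquisition values — with an overall channel
SD of 10 µV. Two class-conditional effects drive the classifier's target:
`asymmetry_effect` multiplies left-hemisphere alpha amplitude by
$1 + \text{effect}$ for responders only, and `complexity_effect` scales
the responders' broadband mixing fraction, shifting fine-scale entropy.
With both at zero the classes are exchangeable by construction. Clinical
score tables are generated to match: integer MADRS-like baselines
(mean 30, SD 5.8, floored at 10) with week-8 reductions drawn uniformly in
[55%, 85%] for responders and [0%, 45%] for nonresponders, with rounding
directions that cannot cross the 50% labelling threshold — so the response
rule recovers the generating class exactly.

What the generator deliberately does **not** emulate: eye-blink and muscle
artifacts, volume conduction and inter-channel correlation, site and
device effects, non-stationarity over minutes, placebo-response mechanics,
or — importantly — between-subject heterogeneity beyond sampling noise.
Every subject of a class is drawn from the same process, and the
asymmetry features are within-subject ratios that cancel global amplitude
differences, so planted class contrasts are recovered with very high
accuracy even when small. Passing tests on synthetic cohorts therefore
demonstrate that the pipeline recovers class-conditional spectral
asymmetry and complexity contrasts when they exist and stays at chance
when they do not — they say nothing about attainable accuracy on clinical
data, where between-subject variability dominates.

All randomness descends from one master seed through a splittable counter
scheme (`derive_seed()`), so per-subject streams are independent of
generation order and every output is a pure function of (specification,
seeds).

## Problem sizes and runtime choices

The test suite and the acceptance script exercise the pipeline at
$n = 60$ per cohort (30 responders / 30 nonresponders) at the default
250 Hz × 120 s conditions, with a 40-subject external cohort; null
calibration permutes labels of a generated null cohort 100 times rather
than regenerating 100 cohorts. These sizes give stable accuracy estimates
(binomial SE ≈ 0.06 at $n = 60$) while keeping a full run in the minutes
range on one core. Structural tests that only exercise plumbing use a
reduced entropy scale range (1–6) and shorter recordings; every scientific
claim about the entropy curve itself is tested at the full 1–70 range.
We do not truncate the MSE scale range in scientific tests: the cost of
the entropy computation is concentrated at fine scales (series length
falls as $1/\tau$), so truncating coarse scales saves little and would
break the three-band partition.

A note on null calibration: leave-one-out accuracy under shuffled labels
is *not* a fair coin. Holding out a subject leaves a 29-vs-30 class
imbalance that votes slightly against the held-out class, so permuted-label
balanced accuracy centres near 0.47 rather than 0.50, and because LOO
predictions share almost all of their training data they are positively
correlated, giving the permutation distribution a wider spread
(SD ≈ 0.08–0.10 at n = 60) than the independent-binomial
SE ≈ 0.065 would suggest. The test suite measures this distribution
directly, and we verified the same mean and spread to three decimals with
an independent scikit-learn nested-LOOCV run on identical permuted labels.
Chance-band checks on LOOCV results should therefore be calibrated against
the permutation distribution itself, not against a binomial band around
0.5.

## Known limitations

* The region map and cleaning stage are reasonable defaults, not
  reproductions of any specific clinical study's unpublished choices; both
  are configuration-replaceable.
* The hyperparameter grid, inner-loop scheme and scaling policy for kNN
  are rarely fully specified in publications; ours are documented defaults
  exposed through `hyperparam_grid()` and function arguments.
* Balanced-accuracy confidence intervals use a normal approximation; no
  exact interval exists for a mean of two proportions.
* The generator's channels are statistically independent; any analysis
  sensitive to cross-channel covariance (connectivity, source modelling)
  is out of scope.
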