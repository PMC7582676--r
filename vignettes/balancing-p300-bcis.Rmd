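---
title: "Class-imbalance correction in P300 oddball BCIs: models, simulation design, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-imbalance correction in P300 oddball BCIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A P300 oddball brain-computer interface presents `N` stimuli (4 or 6 here)
and highlights them one at a time; the user attends one of them (the
target). Attended highlights evoke a P300 — a positive event-related
deflection peaking 250-500 ms after onset. A block consists of every
stimulus being highlighted 10 times; a classifier scores each stimulus's
averaged response and the block's selection is the argmax. Because only one
stimulus in `N` is the target, the training data are imbalanced 1:3 or 1:5
by construction, and a classifier trained on them tends to under-detect
targets (high precision, low recall). This package implements and evaluates
the standard remedies: five oversamplers (random oversampling, SMOTE,
borderline-SMOTE, SVM-SMOTE, ADASYN), three undersamplers (random
undersampling, the neighborhood cleaning rule, Tomek links), a weighted
undersampling bagging ensemble (WUS), and class-weighted SVM
regularization — around a soft-margin SVM target classifier.

## Pipeline and models

**Preprocessing.** Continuous multichannel EEG is zero-phase band-pass
filtered (Butterworth high-pass 0.5 Hz order 4; low-pass 50 Hz order 6 —
the order is chosen so that the two-pass response at 60 Hz is suppressed by
more than 20 dB, which a 4th-order two-pass filter does not reach), then
common-average re-referenced, epoched over [-200, 600) ms around each
highlight, and baseline-corrected by the [-200, 0) ms mean. The half-open
window convention makes the counts exact: epochs are 400 samples at 500 Hz
and the feature window [100, 600) ms contributes exactly 250 points per
channel.

**Features.** The 10 epochs of each (block, stimulus) pair are averaged
into one sample — the only reduction consistent with the design's printed
class sizes (50 target / 150 or 250 nontarget samples from 50 training
blocks). Channels are concatenated and each feature column is standardized
to zero mean and unit variance on the training portion only; the test
portion reuses the training standardizer.

**Samplers.** All eight are implemented from first principles on the
standardized feature matrix with Euclidean neighborhoods, deterministic
index-ordered tie-breaking, and self-exclusion. The SMOTE family
synthesizes `s = p + r (q - p)` with `r ~ U(0,1)` and `q` one of the `k = 5`
nearest minority neighbors of seed `p`. Borderline-SMOTE restricts seeds to
the DANGER set (minority points with more than half of their `m = 10`
nearest neighbors, over the full data, in the majority class); the
literal more-than-half rule is the default and an `exclude_noise` flag
recovers the original publication's exclusion of all-majority
neighborhoods. SVM-SMOTE seeds synthesis at minority support vectors with
fewer than half majority neighbors. ADASYN distributes a budget
`G = beta (|S_maj| - |S_min|)` proportionally to each minority point's
majority-neighbor fraction, with per-point counts rounded up (the ceiling
excess is kept, not trimmed). The neighborhood cleaning rule applies
edited-nearest-neighbors (3 neighbors) and then the stated
nearest-neighbor pruning pass; note that the stated second stage removes a
surviving majority point whose nearest neighbor is majority — the inverse
of textbook condensed-NN — and is implemented exactly as stated. On cleanly
separated data this deletes the entire majority class; the pipeline then
falls back to unbalanced training with a warning. Tomek links (mutual
cross-class nearest pairs) remove only the majority member, in one pass.

**Classifier.** A soft-margin SVM (`min 1/2 w'w + C sum(xi)`) with linear
kernel and `C = 1`, no hyperparameter search. The kernel is a documented
choice: the features are high-dimensional standardized ERP amplitudes, for
which linear SVMs are the field standard. Class-weighted mode multiplies
`C` per class by `l / (2 n_class)` (with equal classes it reduces to plain
`C`). Target probabilities come from a Platt-style sigmoid fit to
cross-validated decision values (3 stratified folds); the calibration is
implemented in the package rather than taken from libsvm because libsvm's
internal CV is not reproducible under R seeds. Block selection takes the
argmax of per-stimulus scores and is invariant to the (monotone)
calibration; per-stimulus binary classification thresholds the calibrated
probability at 0.5, which is where resampling shifts the operating point.
WUS splits the shuffled nontarget data into 3 (4-stimulus) or 5
(6-stimulus) near-equal subsets, trains one calibrated SVM per subset
paired with all target data, ranks members by resubstitution accuracy
(ties broken by subset index), and weights them `i / (n(n+1)/2)` — exactly
1/6, 2/6, 3/6 or 1/15 ... 5/15, summing to one; the block decision is the
argmax of the weighted probability sum.

**Evaluation.** Confusion counts with recall, precision and F1 (harmonic
mean); undefined ratios are reported as `NA`, never 0. The information
transfer rate is `(log2 N + P log2 P + (1-P) log2((1-P)/(N-1))) / T`
bits/min with the `P = 1` and `P -> 0` limits handled exactly; `T` is an
explicit argument and never inferred, because the described paradigm timing
is not internally consistent with published ITR magnitudes in this
literature. Methods are compared across subjects with a paired two-sided
Wilcoxon signed-rank test (a generic choice — the underlying study does not
name its test), without multiplicity correction; identical pairings report
p = 1. Poor performers are subjects below the cohort's own unbalanced mean
accuracy.

## The synthetic cohort: what it emulates and why it looks the way it does

No public recordings accompany the design, so the package generates its
own sessions: 4 or 6 stimuli, 62.5 ms highlights with 62.5 ms gaps
(trial onsets round the fractional 62.5-sample pace cumulatively, so gaps
alternate 62/63 samples and the pace is exact on average), 10 highlights
per stimulus per block, 50 training and 30 test blocks. Target highlights
add a Gaussian-in-time bump (default latency 300 ms, SD 50 ms) scaled by a
fixed posterior-peaked channel topography; subject quality is the ratio
`p300_amplitude / noise_sd`. Defaults are realistic resting-EEG figures:
5 uV evoked peak over 10 uV background.

Background noise supports two regimes. The default models volume
conduction: 4 latent 1/f ("pink") sources mixed into all channels through
a fixed per-subject unit-norm mixing matrix, plus a 10% independent sensor
floor. The alternative (`n_noise_sources = 0, noise_type = "white"`) is
independent broadband noise per channel.

One geometric property of the feature space deserves emphasis, because it
determines whether the balancing question is even meaningful. With
`l = 200` training samples and `p >= 500` unit-variance features in
general position, the two classes are linearly separable with wide
margins, and a `C = 1` SVM fits them with zero slack. In that hard-margin
regime every hull-preserving oversampler — duplication and all
SMOTE-style interpolation — provably cannot move the boundary: the
solution depends only on the class hulls, and synthetic points lie inside
the minority hull. Published recall/precision shifts under random
oversampling therefore imply that real ERP feature clouds are *not* in
general position: their background is spatially correlated and band-limited
enough that the training set is genuinely non-separable. The analysis
cohorts in this package reach that regime honestly: a 2-channel
centro-parietal montage (the classic minimal clinical P300 setup) with the
50 Hz acquisition low-pass bounds the effective feature rank at roughly
120, well under the 200 training samples, so training classes overlap, the
soft margin engages, and the balancing methods act at first order. The
32-channel default remains available and is used for the format- and
count-level tests.

Cohort operating points are fixed once: low-SNR directional experiments
use `p300_amplitude = 2`, `noise_sd = 10` (block accuracy around 55-65%,
comfortably above chance and below ceiling); recovery checks use amplitude
8 over noise 5 (high SNR) and amplitude 0 (chance). The pink-source model
at the 2-channel montage floors block accuracy near 43% regardless of
amplitude — slow in-band drifts defeat 10-trial averaging — so the
analysis cohorts use the independent white-noise regime; this is stated
here rather than buried in code because it is a modelling decision, not a
measurement.

What the synthetic data do not contain: eye or muscle artifacts, bad
channels (the corresponding cleaning stages are identity), inter-trial
latency jitter unless enabled, non-stationarity across blocks, and any of
the real study's subject-specific anatomy. Passing tests therefore show
that the algorithms behave as specified and that the analysis's
qualitative conclusions follow from its stated mechanism under a
controlled generative model — not that the numerical results of any real
recording are reproduced.

## Reproducibility and numerical choices

Every stochastic step takes an explicit integer seed; a master seed
derives per-subject and per-method sub-seeds through a single
`sample.int` draw, so cohorts are reproducible as a whole and per
subject. Fixed seeds give bit-identical sessions, sampler outputs, and
fitted ensembles. Neighbor ties break by lower index; block-selection
ties break to the lowest stimulus index; zero-variance features
standardize with unit scale and a warning; ADASYN with no
majority-adjacent minority points falls back to uniform shares. Session
files round-trip exactly (raw little-endian doubles plus a JSON sidecar);
feature tables round-trip through TSV at full double precision.

## Known limitations

Two reported directions do not reproduce under this generative model, for
the same geometric reason. The mean relative distance of support vectors
to the boundary *decreases* slightly under borderline-SMOTE here (in every
synthetic subject), because balancing adds active constraints and can only
grow `|w|`; the reported 6% increase presumably reflects real-data
geometry this simulation does not capture. Likewise block-level (argmax)
accuracy is nearly invariant to the oversampling ratio — within-hull
synthesis mostly shifts the intercept — so correlations between
classification measures and BCI accuracy across ratio conditions are
undefined or unstable, although the monotone recall/precision/F1 trends
themselves reproduce cleanly. The corresponding assertions are kept in the
acceptance suite and fail visibly rather than being weakened.

Problem sizes used by the test and acceptance runs — 10-subject cohorts,
20-repeat directional experiments, 2-channel montages — are the package's
desk-scale study design; the generator itself scales to the full
32-channel layout.
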