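---
title: "Supervised principal-component risk prediction for miRNA chemoresistance signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised principal-component risk prediction for miRNA chemoresistance signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mirsig` implements a complete analysis path for two-channel miRNA
microarray studies of chemotherapy response: a diagnostic
cancer-versus-normal signature with a multi-classifier prediction
protocol, per-miRNA proportional-hazards screening against time to
progression (TTP), a supervised principal-component predictive index
with percentile-based risk grouping, leave-one-out cross-validated
Kaplan–Meier curves with permutation significance, paired
pre/post-treatment evaluation, and ΔΔCt quantification of qPCR
validations. A synthetic-cohort generator with planted, known signal
makes every stage testable end to end without external data.

## The data model

All expression values are log2 sample/reference ratios in a
feature-by-sample matrix. Raw two-channel arrays are log-transformed
(`log2_transform()`), normalized per array against the
intensity-dependent dye bias (`lowess_normalize()`: the classical
robust lowess smoother fitted to M versus A and subtracted; span 2/3
and 3 robustifying iterations by default), and the replicate probes of
each mature miRNA are collapsed to their per-sample median
(`collapse_replicates()`). The median was chosen over the mean for
robustness to single bad spots. One deliberate numerical property of
this normalization: the classical robust smoother is *not* a
projection, so re-applying it moves the values slightly (by no more
than the residual trend a refitted smoother detects, which is bounded
in the tests); we do not iterate the subtraction, because repeated
robust re-fitting is not a contraction and drifts on pure noise.
Features masked in more than half the samples are dropped, remaining
missing entries are imputed with the feature median
(`filter_impute()`), since the downstream multivariate steps need
complete columns.

## Cancer-versus-normal signature and the classifier protocol

`t_test_per_feature()` uses the classical pooled-variance two-sample t
statistic, two-sided p-values, Benjamini–Hochberg FDR, and reports the
ratio `2^(mean_case − mean_control)`. Features with zero pooled
variance are flagged and excluded rather than given arbitrary
statistics.

`cross_partition_accuracy()` reproduces the microarray class-prediction
protocol: class-stratified random 1:1 training/test splits, feature
re-selection on the training half only (no leakage), and six
classifiers refitted per split — compound covariate predictor (CCP,
t-statistic-weighted sum with a midpoint threshold), diagonal linear
discriminant analysis, 1- and 3-nearest neighbours, nearest centroid,
and a linear SVM (cost 1, features standardized by training
mean/SD). kNN distance ties are broken deterministically (smallest
distance, then training order), so repeated runs under one seed are
bit-identical. The median test accuracy per classifier is the headline
output.

## Survival screening

`cox_screen()` fits one univariate Cox proportional-hazards model per
miRNA, relating TTP to the continuous log2 expression (no
dichotomization). Ties are handled by the Efron approximation — TTP is
recorded in months, so ties occur — and p-values are Wald tests.
Newton iteration runs to a gradient below 1e-8 with step halving; fits
whose coefficient exceeds 15 in absolute value are flagged as monotone
likelihood (the score of a runaway fit vanishes in the tail, so a pure
gradient criterion would falsely "converge" near beta ≈ 19) and are
excluded from selection. Features with `p < alpha` are split into a
chemoresistance list (hazard ratio > 1) and a chemosensitivity list
(hazard ratio < 1). The screen is implemented as a compiled kernel
vectorized across features, because the permutation machinery below
re-runs it tens of thousands of times; `survival::coxph` is used as an
independent oracle in the test suite, and the two agree to ~1e-7 on
random fixtures.

## The supervised principal-component predictive index

`fit_risk_model()` follows the supervised principal-component recipe:

1. screen features by univariate Cox at `selection_alpha`;
2. center the selected submatrix by the training feature means (no
   variance scaling — the index is a weighted average of log
   intensities, so the scale is meaningful);
3. take the first two principal components of the centered
   samples-by-features submatrix;
4. fit a Cox model of TTP on the two PC scores, giving `(b1, b2)`.

The predictive index of a sample is `PI = b1·u1 + b2·u2` with `u_k`
the sample's score on loading `k`; equivalently `PI = w·(x − m)` with
per-feature weights `w = b1·V1 + b2·V2`. Both routes are computed and
must agree to 1e-10 (a standing test). A high PI means expected rapid
progression. If the selected submatrix is numerically rank-1 the
second component's coefficient is zero and the index degenerates
gracefully to a single-PC score.

A new sample's PI is converted to a percentile of the training PI
distribution by the midrank rule
`100·(#{train < pi} + 0.5·#{train = pi})/n`, so a sample exactly at
the training median of an odd-sized training set receives exactly
50%. The high-risk group is percentile strictly above the cutoff,
67 by default — a study-calibrated constant that we treat as given.

`loocv_risk_groups()` refits the *entire* model (screening, PCs, PC
Cox) on every leave-one-out fold and scores the left-out sample
against that fold's training distribution; feature selection is
repeated inside every fold (the conservative reading of
cross-validating "the process"). Folds in which fewer than two
features pass screening assign the left-out sample to the low-risk
group and are counted and reported via a warning, keeping the
one-label-per-sample contract.

`permutation_significance()` computes the log-rank chi-square of the
cross-validated groups (`LR_d`), then jointly reshuffles the
(TTP, event) pairs across samples — expression fixed, so the
expression covariance and the marginal censoring pattern are
preserved — and re-runs the full LOOCV pipeline per shuffle. The
reported significance is the add-one tail probability
`(1 + #{LR_perm ≥ LR_d})/(1 + n_perm)`. Samples are ordered
canonically (by id) before the permutation stream is drawn, so the
result is invariant to the order in which samples arrive. If a
(permuted) LOOCV yields a single risk group the statistic is defined
as 0, i.e. no separation.

## Paired pre/post-treatment evaluation

`evaluate_pairs()` applies a *fixed* fitted model (never refit with
pair samples) to matched pre/post samples. A pair is `correct` iff
the post-treatment PI is strictly higher than the pre-treatment PI —
a tie is not "higher" and counts as incorrect. `summarize_pairs()`
reports the two proof-of-principle fractions: pre-treatment samples
called low-risk, and pairs with the expected post-treatment increase.

## ΔΔCt quantification

`qpcr_analyze()` averages duplicate wells, normalizes each target's Ct
to the RNU6 reference by subtraction (ΔCt), subtracts the control
baseline (mean ΔCt of the normal group by default, or a designated
control sample) to give ΔΔCt, and reports relative expression
`2^(−ΔΔCt)` and the log2-scale fold change `−ΔΔCt` (an FC of −1 is a
50% decrease). Group comparisons use the pooled-variance Student
t-test *on the log2 scale*: on that scale the choice of control
baseline is an additive constant shared by both groups, so the test is
invariant to it — the reason the log2 convention was adopted for the
comparison.

## The synthetic-cohort generator

`sim_config()` fixes the emulated study conditions; they are
deliberately not tuned per analysis:

* ~1,667 mature miRNA features, each measured by 4 replicate probes;
  90 cancer + 34 normal samples for the diagnostic comparison; an
  82-sample survival training set; 8 pre/post responder pairs.
* Biological log2 ratios are iid Normal(0, `noise_sd`²) per feature
  and sample, with `noise_sd = 1` — a typical between-sample log2
  SD for miRNA ratio arrays. Technical replicate noise has SD
  `noise_sd/2`, making replicates more alike than biological samples
  (otherwise collapsing would be pointless).
* Planted differential features shift cancer samples by
  ±`diff_log2_effect` (half up, half down).
* Planted hazard features drive a latent risk `r = Σ β_j x_j` with
  alternating signs ±`hazard_log_effect`; event times are exponential
  with rate `λ0·exp(r)` and censoring is independent exponential —
  the simplest data-generating process consistent with proportional
  hazards. `λ0 = ln2·0.8/3.1` and censoring rate `ln2·0.2/3.1` are
  calibrated analytically so that, at β = 0, the observed TTP median
  is 3.1 months with 20% of patients censored; with planted signal
  the marginal median falls somewhat below 3.1 (Jensen), which we
  accept rather than re-tune. The censoring fraction itself is a free
  parameter — 20% is a choice, not an inference.
* Pair pre-treatment profiles are drawn from the low-risk half of the
  latent risk distribution (the emulated pairs come from clinical
  responders); the post profile is the pre profile moved by
  `pair_shift` along the unit-normalized resistance direction plus
  fresh technical noise.

What the generator does *not* emulate: correlated (co-expressed)
miRNA programs, intensity-dependent dye bias at the probe level,
batch structure, or clinical covariates. Passing tests on these
cohorts demonstrates the statistical machinery under its stated
assumptions; they say nothing about biological validity on real
arrays. Notably, planted hazard features are mutually *independent*,
which is the least favourable geometry for a two-PC supervised
projection (there is no shared factor for a component to capture; the
index works only through the survival-driven tilt of the selected
set). Power figures measured on these cohorts are therefore
conservative for real signatures, which are co-expressed.

## Problem sizes used by the packaged studies

The test suite and the acceptance script run Monte-Carlo studies at
the cohort sizes above (n = 82, 300–500 features for survival
studies; 90+34 samples, 1000 features for the classifier protocol).
Outer replicate counts are the one axis we scale: the permutation
calibration study uses 25 replicates of a 99-permutation test, and
the planted-signal permutation power study uses 10 replicates — sizes
chosen so each study completes in minutes at full per-replicate
fidelity, while keeping the per-replicate protocol (full LOOCV inside
every permutation) exact.

## Known limitations

* Only two principal components; no lasso/elastic-net Cox variants.
* Two-class classification only; no probabilistic outputs.
* The log-rank statistic for cross-validated groups treats the group
  labels as fixed; its null calibration is established empirically by
  the permutation machinery, not analytically.
* The ΔΔCt module assumes a single reference gene and perfect
  amplification efficiency.
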