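# mirsig

miRNA expression signatures and survival risk prediction for
chemotherapy resistance.

`mirsig` is for analysts working with two-channel miRNA microarray
profiles of cancer cohorts who want to (i) derive a diagnostic
cancer-versus-normal signature and estimate its prediction accuracy
honestly, and (ii) build a chemoresistance risk predictor from time to
progression (TTP) under therapy, evaluate it with cross-validated
Kaplan–Meier curves and a permutation test, and apply it to matched
pre/post-treatment biopsies. A synthetic-cohort generator with planted,
known signal makes the entire pipeline testable end to end.

## The statistical core

**Diagnostic signature.** Per-miRNA pooled-variance t tests with
Benjamini–Hochberg FDR and case/control expression ratios
`2^(x̄_c − x̄_n)`; prediction accuracy is the median test-set accuracy of
six classifiers (compound covariate predictor, diagonal LDA, 1-NN,
3-NN, nearest centroid, linear SVM) over class-stratified random 1:1
training/test partitions, with feature re-selection inside every
training half.

**Chemoresistance predictor.** Each miRNA is screened with a univariate
Cox proportional-hazards model (Efron ties, Wald p); features with
p < α split into chemoresistance (HR > 1) and chemosensitivity
(HR < 1) lists. The predictive index is the supervised
principal-component score

&nbsp;&nbsp;&nbsp;&nbsp;PI = β₁·u₁ + β₂·u₂ = w·(x − m),&nbsp;&nbsp; w = β₁V₁ + β₂V₂,

where V₁, V₂ are the first two principal components of the centered,
screened submatrix and (β₁, β₂) come from a Cox regression of TTP on
the two PC scores. New samples are placed on the training PI
distribution by a midrank percentile; percentile > 67 ⇒ high risk
(rapid progression). Significance is assessed by the log-rank
statistic of leave-one-out cross-validated risk groups, compared with
its null distribution under joint reshuffling of the (TTP, event)
labels with the *entire* LOOCV pipeline re-run per shuffle.

**Paired evaluation.** A pair of pre/post-treatment samples is called
correct iff the post-treatment sample gets a strictly higher PI.

**qPCR validation.** ΔΔCt relative quantification against an RNU6
reference, fold changes reported on the log2 scale, pooled t tests
between groups.

## Worked example

```r
library(mirsig)

cfg    <- sim_config(n_cancer = 82, n_features = 300,
                     n_hazard_features = 5, seed = 7)
cohort <- simulate_survival_cohort(cfg)
expr   <- collapse_replicates(cohort$expression, cohort$probe_map)
ttp    <- cohort$clinical$ttp_months
event  <- cohort$clinical$event

sel <- select_survival_features(expr, ttp, event, alpha = 0.05)
head(sel$resistance[, c("feature_id", "p", "fdr", "hazard_ratio")], 3)
#>     feature_id            p         fdr hazard_ratio
#> 3      mir0003 9.898420e-06 0.001484763     1.948915
#> 5      mir0005 8.638019e-05 0.008638019     1.818323
#> 298    mir0298 1.915683e-03 0.114940994     1.503105

model <- fit_risk_model(expr, ttp, event)
#> supervised-PC risk model: 15 features (alpha = 0.05), 82 training samples
#>   PC Cox coefficients: 0.7234, -0.2587; cutoff percentile 67%

cv <- loocv_risk_groups(expr, ttp, event)
table(cv$group)
#> high  low
#>   19   63

permutation_significance(expr, ttp, event, n_perm = 199, seed = 7)
#> cross-validated Kaplan-Meier permutation test: LR_d = 9.527, p = 0.065 (199 permutations)
```

Fifteen miRNAs pass Cox screening at α = 0.05 (8 resistance-, 7
sensitivity-associated); the two leading resistance miRNAs are planted
hazard features of the simulation. The supervised-PC model splits the cohort 19 high / 63 low
risk under leave-one-out cross-validation, and the cross-validated
log-rank statistic of 9.53 sits at the 6.5% tail of its 199-shuffle
null distribution: suggestive separation, not significant at 0.05 on
this particular synthetic draw.

The whole pipeline — simulation, preprocessing, class comparison,
survival screening, risk prediction, paired evaluation, qPCR — runs
under one configuration via `run_pipeline()` (or
`inst/scripts/run_pipeline.R` from a shell), writing TSV tables, KM
curves and a JSON run report; outputs are byte-identical across reruns
with the same seed.

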