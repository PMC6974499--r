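# ssmpca

Scaled Subprofile Model PCA (SSM PCA) for deriving, scoring, and
validating disease-related spatial covariance patterns in metabolic brain
images (FDG-PET and similar), in R.

## The problem

Neurodegenerative diseases such as Parkinson's disease alter glucose
metabolism across whole brain networks, not in isolated regions.  Rather
than testing voxels one at a time, spatial covariance analysis extracts a
single voxel-weight map — a *disease-related pattern* — from a set of
control and patient scans, and then quantifies how strongly any new scan
expresses that pattern as one number (the subject score, or topographic
profile rating).  Expression scores support individual-level assessment:
diagnosis support, progression tracking, treatment monitoring.

This package is for imaging methodologists who want a reproducible,
scriptable SSM PCA pipeline with every convention explicit: masking,
log-transform and double centering, voxel-space PCA, component selection,
logistic combination, bootstrap voxel stability, per-camera z-scoring,
and cross-cohort validation statistics.

## The model

For subject *i*, voxel *v*: `log y_iv = alpha_i + g_v + r_iv`, with
subject offset `alpha_i`, group mean profile (GMP) `g_v`, and subject
residual profile (SRP) `r_iv`.  PCA of the SRP matrix gives orthonormal
voxel loadings; the components explaining the top 50% of variance enter a
forward stepwise logistic regression (AIC), and the selected components,
weighted by their regression coefficients, are combined into a unit-norm
pattern *w*.  A new scan's raw score is the inner product of its residual
profile (computed against the *stored* derivation GMP) with *w*; scores
are z-transformed to healthy controls scanned on the same camera.  Voxel
stability is assessed by rerunning the full derivation on bootstrap
resamples and keeping voxels whose one-sided 90% percentile CI excludes
zero.

## Worked example

Everything is testable without clinical data through the bundled
synthetic-cohort generator (known ground-truth pattern and expression
scores):

```r
library(ssmpca)

co  <- generate_cohort(synthetic_cohort_spec(seed = 1))   # 20 HC + 20 PD
fit <- derive_pattern(co$volumes)
fit$pattern
#> covariance_pattern: 6136 voxels, components [1, 2, 5, 6, 10, 13]
#>   coefficients: 47.8, 8.67, 12.2, 30.3, 30.4, 14.4; variance fractions: 0.119, 0.0267, 0.0257, 0.0255, 0.0249, 0.0243
#>   derived from 20 controls / 20 patients

val <- generate_cohort(synthetic_cohort_spec(seed = 1000004))  # held out
sc  <- score_cohort(val$volumes, fit$pattern)
discrimination_report(sc)
#> discrimination_report: AUC = 0.880 (HC n=20, PD n=20); t = 5.27, p = 5.79e-06

bt <- bootstrap_stability(co$volumes, n_replicates = 200, seed = 1)
bt
#> bootstrap_result: 200 replicates (0 degenerate), one-sided 90% CI
#>   stable voxels: 514 of 6136 (8.4%)
```

Reading the output: principal component 1 carries 11.9% of residual
variance (the disease signal); the stepwise search also admitted several
small components — see the methods vignette for why that happens with a
flat noise spectrum and when to prefer `derive_pattern_pc1()`.  On the
held-out cohort the pattern separates groups with AUC 0.88 and a strongly
significant t test, and the bootstrap concentrates its 514 stable voxels
on the true pattern foci.

Patterns are saved/loaded as NIfTI + JSON bundles (`write_pattern()`,
`read_pattern()`), cohorts as NIfTI files plus a TSV manifest.  A thin
command-line front end (`exec/ssmpca`) exposes
`simulate / derive / bootstrap / score / validate / compare` over the
same functions, writing a reproducibility manifest per run.

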