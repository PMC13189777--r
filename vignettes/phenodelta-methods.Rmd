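---
title: "Methods: PhenoAge scoring and the two-stage lifestyle analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PhenoAge scoring and the two-stage lifestyle analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenodelta)
```

## The model

PhenoAge treats a panel of routine clinical biomarkers as predictors of
10-year (120-month) mortality under a Gompertz hazard, and reports the
age at which a reference person would carry the same risk. Three maps are
composed:

1. **Linear predictor.** `xb = b0 + Σ bj·xj` over the covered markers, in
   fixed units (albumin g/L, creatinine µmol/L, glucose mmol/L, MCV fL,
   WBC 10³/µL, age years; CRP, when covered, enters as its natural log).
   The ten-term weights, the Gompertz rate γ = 0.0076927/month, the
   120-month horizon, and the inversion constants are configuration, not
   code: they ship as a versioned YAML file
   (`inst/extdata/levine2018-phenoage.yaml`, md5-checksummed at load) and
   any file with the same schema can replace it. The six-marker variant
   used with TWB-style panels keeps the original intercept and weights and
   simply drops the four unavailable terms; this is the only reading
   consistent with coefficients being adopted unchanged, and the
   downstream sex-specific linear calibration absorbs the systematic
   offset the truncation introduces.
2. **Gompertz risk.** `risk = 1 − exp(−exp(xb)·K)` with
   `K = (e^{120γ} − 1)/γ`. Strictly increasing in `xb`, onto (0, 1).
3. **Age-scale inversion.** `offset + log(scale·(−log(1 − risk)))/rate`,
   strictly increasing in risk.

The sex-specific calibration from the six-marker score to PhenoAge is
linear with published constants (men: 45.846752 + 1.068403·x; women:
46.527973 + 1.023272·x). ΔPhenoAge is the follow-up minus baseline
PhenoAge; ΔAge, the follow-up gap in decimal years, is the corresponding
observation window.

### Numerical choices

In double precision `risk` saturates at 1 once `exp(xb)·K` exceeds ~36
(`xb ≳ −1.7`), so composing steps 2–3 through the risk would overflow for
high-risk panels. The composition is therefore evaluated in log space,
where it is exactly affine: `phenoage(xb) = offset + (log(scale) + xb +
log K)/rate`. The public inversion also accepts a pre-computed
`log(1 − risk)` for complements too small to represent, and computes
`log1p(-risk)` otherwise. Monotonicity of the risk map is
property-tested on `xb ∈ [−30, −2]`, the widest grid on which the closed
form stays strictly inside (0, 1) in double precision.

## Stage 1: partial-correlation screen

For each factor the Pearson correlation between the residuals of the
factor and of ΔPhenoAge, after both are regressed on an intercept plus
the adjusting covariates (sex and ΔAge in the pooled run), is computed
from a QR decomposition. Inference follows the convention of the standard
partial-correlation implementations: `t = r·sqrt((n − 2 − k)/(1 − r²))`
on `n − 2 − k` degrees of freedom, two-sided, with `k` the number of
covariates; the 95% interval is Fisher-z with standard error
`1/sqrt(n − 3 − k)` and the normal critical value 1.96 — at the cohort
sizes this pipeline targets (tens of thousands) the difference from a
t-based critical value is far below the reported precision. Ordinal 1–5
and 1–3 items are correlated as numeric scores, matching how such
questionnaire items are conventionally screened.

The screen is deliberately exploratory: 43 factors at raw p < 0.05, no
multiplicity correction by default (a `p_adjust` switch exposes
Bonferroni/BH for users who want it). Missing data are handled by one
global complete-case filter with a logged count; constant columns are
excluded with a warning rather than an error so that one degenerate
factor cannot abort a screen.

## Stage 2: exact best-subset selection

Within each sex stratum, all `2^m` subsets of the screen-selected
candidates (ΔAge always forced in) compete on the Gaussian AIC
`n·log(rss/n) + 2(k + 2) + n(log 2π + 1)`; the full constant is included
so values match standard software, and it cancels in comparisons at fixed
`n`. The default search is a branch-and-bound over an
include/exclude tree on candidates ordered by full-model explanatory
weight: since RSS never increases when predictors are added, the RSS of a
node's fullest completion bounds every completion's AIC from below, and a
branch is pruned only when that bound cannot beat the incumbent — the
returned set is therefore the provable global minimum, which the test
suite verifies against exhaustive enumeration. Subset RSS values come
from Cholesky solves on the Gram matrix, so cost per subset is `O(p³)` in
the number of predictors, not the number of rows. Ties (within 10⁻⁹ AIC)
break toward fewer predictors, then lexicographic label order —
parsimony first. More than 30 candidates are refused with guidance rather
than silently truncated. Sex is not a candidate or covariate in stage 2
because the strata are disjoint by sex.

Standard errors and p-values of the selected model are the naive OLS
ones; selection-adjusted inference is intentionally not attempted, and
coefficients should be read accordingly. Variance inflation factors
(`1/(1 − R²_j)` of each predictor on its co-predictors) are reported per
model; perfect collinearity yields an infinite VIF flag rather than an
error. `aic_gaussian(0, …)` returns −∞ with a warning so a perfect fit
dominates any selection rather than crashing it.

## The synthetic cohort generator

The generator exists so that every pipeline stage can be exercised and
validated end to end without the access-controlled source data. Its
defaults are the published study conditions, fixed once:

- sex mix 36.5% male; follow-up gap truncated normal on [1.6, 15.9]
  years with per-sex means 4.91/4.88 and SDs 1.51/1.53 — the configured
  mean is the mean of the *truncated* law (the parent location is solved
  numerically to offset truncation bias);
- baseline age truncated normal (men 50.15 ± 11.28, women 49.87 ± 10.41,
  bounds 20–90);
- ordinal and binary factors drawn at the published per-sex prevalences
  (shipped as `twb_reference_counts()`); 1–5 diet items and education as
  discretized normals at the published means/SDs (discretization shifts
  means by up to ~0.1 point — acceptable since no calibration target
  asserts diet means);
- obesity-index changes at the published mean changes; their SDs are not
  published, so realistic values were fixed once (ΔBMI 1.3 kg/m², ΔBFP
  3.0%, ΔWC 4.5 cm, ΔHC 3.0 cm, ΔWHR 0.04);
- outcome `ΔPhenoAge = intercept_sex + Σ β_j·x_j + β_ΔAge·ΔAge + ε`,
  `ε ~ N(0, 3.3²)` years, with the published per-sex coefficient patterns
  planted by default and the per-sex intercept calibrated at generation
  time so the mean outcome matches the published 4.75 (men) / 4.61
  (women) years; the noise SD 3.3 puts the planted male model's adjusted
  R² in the neighborhood of the published ~25%;
- factors are drawn independently; real questionnaire items are
  correlated, so the generator's VIFs sit near 1 while real-data VIFs
  reached ~1.6. A user-supplied correlation structure can be emulated by
  post-processing, but no joint dependence is asserted as truth because
  none is published.

**Biomarker back-fill.** Baseline PhenoAge is chronological age plus a
truncated-normal cross-sectional offset (men −5.18 ± 4.0, women
−7.86 ± 3.6, truncated at ±3.5 SD); follow-up PhenoAge adds the planted
ΔPhenoAge. Each visit's six-marker panel is then constructed by drawing
MCV, WBC, albumin and creatinine around realistic reference levels and
solving the scoring chain exactly for fasting glucose — the score is
strictly monotone in glucose, so this one-dimensional inversion is
well-posed. If the solved glucose falls below 0.3 mmol/L (a tail event,
~1% of rows), the remaining deficit moves into MCV so every marker stays
strictly positive and the inversion stays exact. Scoring the generated
panels reproduces the planted ΔPhenoAge to ~10⁻¹³ years, verified on
every generated row in the tests.

What passing tests on these cohorts shows: the pipeline's statistical
machinery (screen calibration, exact selection, coefficient recovery) is
correct under the generating model. What it does not show: robustness to
correlated factors, non-linear effects, informative missingness, or
biomarker physiology — none of which the generator emulates.

## Validation studies and their expected behavior

`type1_error_study()` screens a pure-noise factor against a pure-noise
outcome (n = 1,000, 2,000 replicates by default) and checks the p < 0.05
rejection rate against the binomial 95% band around 0.05.

`recovery_study()` generates all-male cohorts of n = 25,000 (matching
the published male stratum) with the published male pattern planted, runs
both stages, and reports (a) the rate at which every *detectable* planted
factor — implied partial correlation `|β|·sd(x)/3.3 ≥ 0.02` — survives
screen plus selection, and (b) per-coefficient coverage of the planted
values within three estimated SEs on refitting the generating set. The
detectability bound matters: AIC admits any predictor whose `t²` exceeds
2, so planted factors with implied correlations near or below ~0.015
(e.g. the weakest published diet and employment effects at these sample
sizes) cannot be recovered reliably by any exact-AIC pipeline, and
incidental inclusion of a few noise factors is expected behavior, not a
defect. Three of the detectable factors sit near the 0.02 boundary
(implied ρ ≈ 0.024–0.026, i.e. t ≈ 3.8–4.0), where the joint probability
of surviving both stages is ~0.95–0.98 each; the joint support-recovery
rate therefore has expectation around 0.89–0.92 and will hover at the
0.9 mark. Per-coefficient coverage is comfortably above 95%.

Problem sizes used throughout the suite (40–80 rows for oracle
equivalence, 1,000–25,000 for calibration and recovery, 50–2,000
replicates) were chosen so each study's Monte-Carlo error is small
relative to the contract it checks.

## Determinism and provenance

All randomness flows from a single seed; the same seed reproduces a
cohort byte for byte. Report CSVs carry provenance comment headers
(package version, seed, configuration hash). Headers deliberately carry
no timestamp: rerunning the same configuration must produce identical
bytes.

## Known limitations

- The six-marker score is a calibration of, not a substitute for, the
  ten-term score; panels missing any of the six markers are rejected, not
  imputed.
- Stage-2 inference is post-selection-naive by design.
- Generator factors are mutually independent; multicollinearity behavior
  of real questionnaires is not reproduced.
- The screen treats ordinal items as numeric scores; rank-based
  alternatives are out of scope.
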