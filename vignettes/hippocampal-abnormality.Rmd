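---
title: "Normative multivariate scoring of hippocampal abnormality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative multivariate scoring of hippocampal abnormality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippomahal)
```

## The problem and the model

Hippocampal pathology in drug-resistant epilepsy is spatially heterogeneous:
one patient's abnormality may sit in the CA–dentate complex, another's in the
SRLM or the tail, on either side. A univariate group test on any single
volume therefore dilutes effects that are individually strong but
anatomically scattered. This package quantifies *overall* structural
deviation per subject instead, in four steps.

**Harmonization.** Volumes from different scanners/sequences carry additive
and multiplicative batch effects. `combat_fit()` fits, per feature (each of
the 10 hemisphere × measure volumes, harmonized jointly so the
empirical-Bayes step can borrow strength across features), a linear model
with batch indicators and the biological covariates to preserve — sex, age,
and presence of epilepsy (a single binary indicator; the responder /
non-responder distinction is deliberately *not* in the design, so that any
response-related signal survives harmonization). Residuals are standardized
by the pooled variance; per-batch location γ and scale δ² estimates are
shrunk with a normal prior on γ and an inverse-gamma prior on δ², moments
matched across features, iterated to a tolerance of 1e-4 (max 100
iterations). `combat_apply()` is a separate step so the fitted adjustment can
be serialized (`combat_to_json()`) and audited; it refuses batches unseen at
fit time rather than extrapolating. A single-batch cohort yields an identity
adjustment with a warning. With `eb = FALSE` the raw location/scale estimates
are used, which exactly equalizes batch moments in a covariate-free design.

**Normative z-scoring.** `fit_normative()` fits `volume ~ age + sex` by OLS
on controls only, per hemisphere × region, and stores the control residual
SD with denominator n − p (unbiased under the fitted model). `zscore()` then
standardizes every subject — controls included, with no leave-one-out — so a
control cohort has per-feature mean z of exactly 0 and sample SD
√((n − p)/(n − 1)). Sex enters as a single binary indicator and age linearly;
no quadratic age term is fitted.

**HOI selection.** `select_hoi()` picks, per subject, the hemisphere with
the smaller mean z over the four sub-regions — the more atrophic side. The
mean and the sum criteria order hemispheres identically over a fixed region
set, so the rule is implemented once as the mean. Exact ties fall back to
the smaller whole-hippocampus z, then to the left side; with continuous data
ties are measure-zero, so the tie-break is a determinism device, not a
scientific choice.

**Mahalanobis scoring.** `fit_reference()` estimates the control mean vector
μ and covariance C (denominator n − 1) of the four-region z-vectors, and
`mahalanobis_score()` computes M = √((Z − μ)ᵀC⁻¹(Z − μ)) via Cholesky
factorization and triangular solves — no explicit inverse — for numerical
stability. M is direction-agnostic (atrophy and hypertrophy at equal
displacement score equally) and affine-invariant. By default the control
reference is built from the controls' *own* HOI vectors, selected with the
same rule as patients, so patient and reference vectors share the
selection-induced distribution; `mode = "pooled"` (both hemispheres of every
control) is available because either convention is defensible — the pooled
reference has a less negative μ, since HOI selection picks each control's
worse side. A ridge of 1e-8 · trace(C)/4 is added only if C is
near-singular; a covariance that remains singular is an error rather than a
silent pseudo-inverse.

## Group statistics

Comparisons are one-tailed Wilcoxon rank-sum tests, with the direction fixed
a priori per measure: abnormality (Mahalanobis) *greater* in non-responders,
volume z *smaller*. The default p-value uses the normal approximation with
tie-corrected variance and continuity correction; an exact-enumeration mode
exists for small, tie-free samples. Effect sizes are rank-biserial
correlations, r = 2·AUC − 1 exactly, with AUC from the Mann–Whitney identity
(ties counted ½). Qualitative labels default to thresholds (.1, .3, .5);
`thresholds = "field"` selects (.1, .2, .4), the convention under which
r ≈ .22 reads as a medium effect in the epilepsy-morphometry literature.

The multiple-comparison family is the four per-region tests only — the
whole-hippocampus and Mahalanobis comparisons are separate headline tests,
which is why a Bonferroni factor of 4 appears in the region family.
Benjamini–Hochberg and Bonferroni come from `stats::p.adjust`; the
harmonic-mean p is the plain unweighted harmonic mean, with an
asymptotically calibrated significance level available
(`harmonic_mean_p(..., calibrated = TRUE)`): under the global null the
reciprocal of the harmonic mean of L p-values follows a Landau distribution
with location log L + 0.874 in the standard-density convention
φ(x) = π⁻¹∫₀^∞ exp(−t log t − xt) sin(πt) dt, whose tail the package
integrates numerically. The plain harmonic mean is the reported statistic;
the calibrated level is strictly larger, the plain mean being
anticonservative as a p-value.

Contingency tests apply the Yates continuity correction exactly when the
table is 2×2 — this is the convention under which the package's demographic
tables reproduce standard published statistics — and never otherwise. ANOVA
is the ordinary one-way F test. One published sex-by-group statistic
(χ² = 4.65 with p = .199 for a 2×3 table) is internally inconsistent — that
p implies 3 degrees of freedom — and is deliberately not asserted anywhere.

## The synthetic cohort

`simulate_cohort()` draws the cohort the analysis assumes, with defaults
fixed once as the study conditions:

* **Sizes:** 100 controls, 42 responders, 50 non-responders.
* **Volumes:** bilateral four-region draws from an 8-dimensional Gaussian
  with compound-symmetric correlation ρ = .6 — the minimal structure that
  makes the multivariate/univariate contrast meaningful — scaled by
  per-region SDs; base means (CA-DG 1300, SRLM 420, subiculum 560, tail
  550 mm³) and SDs chosen as typical subfield volumetry magnitudes.
* **Covariates:** age uniform on 17–71 years with linear decline of roughly
  0.15%/year per region; a male-larger sex effect of about 7%; group-specific
  sex and scanner-assignment probabilities matching the emulated cohort's
  margins (controls scan 30:70 FSPGR:MPRAGE, patients roughly 60:40).
* **Batch effects:** the second sequence adds 0.4 region-SD to each volume
  and inflates noise SD by 15%.
* **Abnormality:** a mean shift of 3 control-SDs in one randomly chosen
  region (SRLM shifts ×1.25, echoing its largest univariate effect), on one
  random side with probability .8, atrophic with probability .85, injected
  in 60% of non-responders and 20% of responders. Abnormality is a mean
  shift, not a variance change. A rare extreme draw that would take a volume
  non-positive is floored at 5 mm³, since subfield volumes are anatomically
  positive.
* **Clinical covariates:** lesion, hippocampal-sclerosis and TLE/ETLE labels
  assigned with the emulated cohort's exact frequencies, including
  missingness, so Table-style demographic tests are exercised end-to-end.

The generator emulates the *statistical* structure only: no segmentation
error, no hemispheric asymmetry of means, no hippocampal allometry, no
age-by-disease interaction. Passing tests therefore demonstrate that the
pipeline recovers known structure under its own assumptions — not that those
assumptions hold in any particular clinical sample.

## Numerical choices and degenerate inputs

* Quadratic forms by Cholesky; explicit `solve()` appears only in test
  oracles.
* EB iteration stops when successive γ*, δ* change by < 1e-4 relatively.
* Zero residual variance, rank-deficient designs, single-sample batches,
  singular covariances, one-class ROC labels, zero-marginal contingency
  tables and all-tied rank comparisons raise informative errors or warnings
  rather than NaNs (an all-tied comparison reports p = 1 with a warning).
* Whole-hippocampus volume, when absent from the input, is the sum of the
  four sub-region volumes per hemisphere — the only construction available
  from the parcels.
* `sensitivity_exclude()` deliberately reuses the main run's harmonization,
  normative models and control reference: exclusions target patients, and
  the control-defined reference should not move under a patient-side
  sensitivity analysis.

## Problem sizes in the tests

The test-suite simulations are sized to exercise each claim at the smallest
scale that still pins it down: coefficient-recovery and coverage checks use
100-subject control cohorts over 60–100 seeds; the null-calibration check
runs 150 full cohorts with the abnormality effect switched off; the
multivariate-vs-univariate contrast runs 100 full cohorts; the rank-sum
size check uses 10,000 two-sample draws; distributional checks (χ²₄ of M²)
use 5,000 vectors. The acceptance script mirrors these sizes.

## Known limitations

* Harmonization supports exactly the location–scale parametric-EB model: no
  reference-batch mode, non-parametric priors, CovBat or longitudinal
  variants, and no extrapolation to unseen batches.
* The normative model is linear in age; strongly non-linear ageing would
  call for GAM-type normative models, which are out of scope.
* Re-harmonizing already-harmonized data is only approximately idempotent:
  the second pass re-estimates batch effects with sampling noise of order
  √(2/n_b), so individual values can move by a few percent of a feature SD
  even though nothing systematic remains — a property shared with the
  canonical implementation.
* The 8-region (both-hemispheres) Mahalanobis variant and HS-excluded
  sensitivity rerun are available through the exported functions but are not
  part of the default report.
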