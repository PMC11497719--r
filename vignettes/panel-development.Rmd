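---
title: "Developing, validating and interpreting a multimarker plasma panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing, validating and interpreting a multimarker plasma panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the methods account of **plasmapanel**: the models and
procedures it implements, the assumptions behind them, the tunable
parameters with their defaults, and the design decisions taken where the
methodology left genuine freedom. The workflow targets plasma P-tau181,
GFAP, NfL (pg/mL) and the unitless Abeta42/40 ratio, measured in
memory-clinic populations, for six diagnostic contrasts: amyloid status in
the whole clinic population (`Q1`) and in pre-dementia stages (`Q2`), and
the differential contrasts AD vs FTD (`Q3`), amyloid-negative-SCD controls
vs FTD (`Q4`), AD vs DLB (`Q5`) and controls vs DLB (`Q6`).

## Cohort data model

A cohort is one row per subject: id, age, sex, diagnostic group (`SCD`,
`MCI`, `AD_dementia`, `FTD`, `DLB`, plus `control_other` for forward
compatibility with volunteer groups — excluded from all six built-in
questions), amyloid status and the four plasma markers. Two rules are
enforced at validation: concentrations must be strictly positive (the
ratio in (0, 1)), and AD-dementia subjects must be amyloid-positive,
mirroring how such patients are recruited (a biological AD diagnosis
requires abnormal amyloid). Subjects with missing markers are *retained*
and counted in a load report; they are dropped per question
(complete-case) only at fitting time, so a marker missing for one model
never silently removes a subject from another. Subjects with unknown
amyloid status stay in the table and are excluded at question-subsetting
wherever amyloid defines the outcome or the control arm.

Column mapping is configurable at load (`read_cohort(schema = ...)`)
because source cohorts rarely share header conventions.

### Amyloid adjudication

`adjudicate_amyloid()` encodes the reference-standard rule table used in
clinical practice: an amyloid-PET visual read (or centiloid > 30 when
only quantification exists) takes precedence over CSF; CSF rules are
assay-specific — Innotest P-tau181/Abeta42 > 0.06, Elecsys ratio > 0.02,
Lumipulse Abeta42/40 < 0.069 (Abeta42 < 725 pg/mL when Abeta40 is
missing), Innotest Abeta42 < 880.5 pg/mL, and Lumipulse ratio < 0.062 for
an alternatively calibrated Lumipulse assay. The rule table is
deterministic and total; evidence
conflicts within a precedence tier resolve to the first-listed modality
with a warning, so batch adjudication never stalls on a discordant
subject.

## Harmonization

**Passing–Bablok regression** aligns marker values measured with
different assay kit lots. We implement the classical
positive-correlation (part-I) algorithm — appropriate because
re-measurements of the same samples are strongly positively correlated by
construction: the slope is the shifted median of all pairwise slopes
(pairs with equal x, and slopes exactly −1, excluded; shift K = number of
slopes < −1; even counts average the two central order statistics), the
intercept is `median(y − b·x)`, and 95% intervals come from the standard
rank-based normal approximation. Monte-Carlo checks in the test suite
show near-nominal interval coverage at n = 35 pairs, the size of a
typical re-measurement panel. `apply_alignment()` is the affine map; it
flags (rather than clips) aligned values that land non-positive. Because
Youden thresholds are rank-based, aligning a cohort and recomputing a
threshold commutes with transforming the threshold — a property the test
suite verifies and that practitioners rely on when moving cutoffs
between lots.

**NfL age correction.** Plasma NfL rises strongly with age, so the models
use an age-corrected value. The published reference-curve coefficients
are not redistributed here; the default correction is therefore the
*identity*, with a documented `log_linear_reference` form
(`nfl / exp(b0 + b1·age)`, the observed-to-age-expected ratio) for users
who have coefficients. Under the identity default, `nfl_age_corrected`
equals raw NfL; all machinery downstream is agnostic to which was used.

## Marker selection

Selection follows the bootstrapped-LASSO recipe. Two decisions deserve
emphasis:

* **Linear, not logistic, LASSO.** The penalty is tuned toward minimal
  mean squared error in 10-fold cross-validation; MSE is the linear-model
  CV criterion, so the 0/1 outcome is treated as a numeric response in an
  L1-penalized linear regression (`glmnet`, gaussian family; its `lambda`
  is the penalty called alpha in this literature — the objectives
  coincide with scikit-learn's `Lasso`).
* **Standardize inside each resample.** Predictors are z-scored within
  every bootstrap resample and CV training fold (the outcome stays 0/1).
  This makes selection frequencies invariant to affine rescaling of any
  marker, which the tests verify exactly.

The penalty is tuned once per question and then held fixed across the
bootstrap (consistent with one optimal penalty per question being the
natural summary of this procedure); the default grid is 60 log-spaced
values on [1e-4, 1], comfortably covering the optima seen in practice
(~0.01–0.12). Resamples that come up single-class are redrawn and
counted, keeping the denominator at the nominal number of iterations
(default 1000). "Selected" means |coefficient| > 1e-8. The panel rule is
strict: a marker joins the shared diagnostic panel iff its selection
frequency is exactly 100% for at least one question — 99% does not count.

One property of the synthetic generator matters when interpreting
selection results on simulated data: with the default group moments, the
Abeta42/40 ratio has equal means but unequal SDs between `Q4`'s arms,
which is a weak but genuine signal; at small tuned penalties the ratio is
therefore selected far more often on synthetic cohorts than on real
clinical data, where it carries no incremental information next to
P-tau181. This is a fidelity limit of moment-matched marginals, not a
selection bug; the suite asserts the robust pattern (NfL and GFAP at
100% for controls-vs-FTD, null selection decreasing in the penalty).

## Question models and thresholds

`fit_question_model()` fits a maximum-likelihood logistic regression on
*raw* marker units, so the serialized coefficients apply directly to
pg/mL inputs — the JSON model file written by `write_question_model()` is
the deployable interpretation artifact. Perfect separation fails loudly,
naming the separating marker. For `Q3`/`Q5` the positive class is AD; for
`Q4`/`Q6` it is the dementia group (FTD/DLB); orientation is recorded in
the model object.

Thresholds are deliberately computed **without** cross-validation on the
full development data (they are clinical operating points, not
generalization estimates), while the ROC-AUC **is** cross-validated
(10 stratified folds, model refit per training fold, out-of-fold
probabilities pooled, DeLong 95% interval on the pooled scores). For a
single marker the raw value is the score — by monotone invariance of the
AUC no per-fold refit is needed.

Candidate cutoffs are midpoints between adjacent distinct observed values
plus the two boundary cutoffs; Youden ties break toward higher
specificity, then the smaller absolute cutoff. The 90%-sensitivity
threshold is the largest cutoff with sensitivity ≥ 0.90 and the
90%-specificity threshold the smallest with specificity ≥ 0.90 (the ≥
reading of "at 90%"; nearest-to-90% was the alternative).

**Likelihood zones.** The natural rule-out/rule-in construction pairs
*low* likelihood with probabilities at or below the 90%-sensitivity
cutoff (at most 10% of true cases are missed there) and *high* with
probabilities at or above the 90%-specificity cutoff, the band between
being indeterminate — this is the default `zone_convention =
"sensitivity_specificity"`, and with moderately discriminating panels it
yields the substantial indeterminate fractions seen in practice. The
literal textual pairing of the thresholds the other way around is
available as `zone_convention = "literal"`. When a panel separates so
well that the 90%-sensitivity cutoff exceeds the 90%-specificity cutoff,
the zones would invert; the model flags this and interpretation degrades
to the Youden cutoff alone. The high-side boundary is inclusive.

## External validation

A frozen development model is transported without refitting.

* **Case-mix (membership) model:** logistic regression of cohort
  membership on the panel markers plus, by default, the question outcome;
  its pooled out-of-fold CV-AUC quantifies how different the validation
  case mix is (low ≈ reproducibility setting, high ≈ transportability
  setting). No hard cutoff is imposed — the quantity is reported, not
  classified.
* **Discrimination:** AUC of the frozen probabilities, plus accuracy,
  sensitivity, specificity and the confusion matrix at the *development*
  Youden probability cutoff (using the transported cutoff is the point;
  0.5 would flatter a miscalibrated model).
* **Calibration:** calibration-in-the-large is the intercept of a
  logistic recalibration with the frozen linear predictor as offset
  (perfect 0); the calibration slope is the coefficient of the linear
  predictor with a free intercept (perfect 1). The calibration curve uses
  decile bins (the TRIPOD convention) of predicted probability with
  per-bin observed rates, plus a Loess smooth (span 0.75, degree 1,
  sampled on a 100-point grid, clipped to [0, 1]); bins thinner than 5
  subjects trigger automatic bin reduction.
* **Threshold transportability:** per-marker Youden cutoffs and the three
  probability thresholds are recomputed on the validation subset and
  reported next to the development values with relative differences
  (default flag level 20%).

The test suite verifies the recalibration estimators by parameter
recovery: data generated from the frozen model itself gives CITL ≈ 0 and
slope ≈ 1; a +1 linear-predictor offset gives CITL ≈ +1; a doubled linear
predictor gives slope ≈ 2 (n = 20,000 per check).

## Interpretation graphics

`upset_summarize()` classifies each subject normal/abnormal per marker at
the Youden cutoffs and tabulates all 2^k combination patterns, including
empty ones, with cohort fractions and outcome composition; patterns are
ordered by descending count (ties by pattern binary value). The plot is
the matrix-dot UpSet layout with outcome-stacked bars; a highlight box
marks a single patient's combination, and cross-module consistency
(highlighted pattern equals the classifier's flag pattern) is tested.

`density_spec()` estimates per-class probability densities with a
Gaussian kernel, Silverman's bandwidth and boundary reflection at 0 and 1
(renormalized to integrate to 1 on the grid within 1e-3); classes with
fewer than five subjects fall back to a rug with a warning. Threshold
lines are drawn vertically on a probability x-axis (an orientation
choice; the same thresholds could be drawn horizontally on a flipped
layout). `patient_report()` composes the value-vs-threshold table, the
boxed UpSet and the density with the patient's probability line into one
page; figures can be written as SVG or PNG (300 dpi).

## The synthetic cohort generator

The generator exists so that every operation above is exercisable and
testable without patient-level data. Its defaults encode a realistic
memory-clinic case mix in seven strata (amyloid-stratified SCD and MCI,
AD-dementia, FTD, DLB; total n = 1199) with published-style per-group
marker means and SDs, age distributions, sex ratios and
amyloid-positivity mixtures for the clinically defined groups (AD 100%,
FTD 17%, DLB 49%).

Design choices:

* **Lognormal marginals**, moment-matched via
  `sigma² = ln(1 + sd²/mean²)`, `mu = ln(mean) − sigma²/2`. Several group
  SDs approach or exceed the means (FTD NfL 38.3 ± 38), so normal
  marginals would generate impossible negative concentrations; the
  lognormal preserves the printed mean/SD exactly while staying positive
  and right-skewed, as concentration data are.
* **Gaussian copula, uniform pairwise correlation 0.3.** True
  inter-marker correlations are not published; 0.3 is a plausible,
  configurable default. Acceptance-level checks (moment fidelity, AUC
  ordering) are insensitive to it within reason.
* **Age and markers independent within group** by default (the printed
  summaries do not constrain the coupling); a `nfl_age_effect` hook adds
  a log-linear age effect to NfL for testing the age-correction
  operation.
* **FTD/DLB markers pool over the amyloid label** (their printed
  summaries pool them); an optional `abeta_pos_shift` creates sharper
  co-pathology structure for experiments.
* **Site shifts** (per-marker affine maps applied last) emulate a
  different kit lot, closing the loop with the Passing–Bablok module.

What passing tests on synthetic cohorts do and do not show: they
demonstrate that the estimators, thresholds and workflow are correct and
internally consistent under a controlled data-generating process whose
marginals match published summaries. They do **not** demonstrate
clinical performance on real cohorts — the generator has no true
covariance structure, no age–marker coupling by default, no batch or
storage effects, and (as noted under marker selection) its Abeta42/40
marginals create a weak artificial signal in one contrast. Reported AUCs
on synthetic data are properties of the generator, not of patients.

## Problem sizes and numerical conventions

The test suite uses n = 100,000 single-group draws for generator-fidelity
checks (3-standard-error bands), n = 20,000 for logistic and calibration
parameter recovery, 200-iteration bootstraps for selection behavior, and
20 randomized small instances per oracle-equivalence property
(Youden-vs-exhaustive-scan, AUC-vs-Mann-Whitney, Passing-Bablok-vs-
pairwise-enumeration) — sizes chosen so the whole suite runs in well
under a minute per file while keeping Monte-Carlo error far below the
asserted tolerances. Numerical conventions collected in one place:
coefficient non-zero tolerance 1e-8; Youden tie-break (specificity, then
|cutoff|); candidate cutoffs as midpoints plus boundaries; density grids
on [0, 1] with reflection; stratified CV folds seeded explicitly;
single-class resamples redrawn, single-class subsets refused.

## Known limitations

* No P-tau217 and no covariate-augmented models (age, sex, APOE, MMSE) —
  the panel reflects a biological state, and covariates are deliberately
  out of scope.
* No longitudinal visits; one row per subject.
* The NfL age correction ships as identity until users supply reference
  coefficients.
* No CSF Elecsys-to-Innotest value transformation (coefficients not
  redistributable); the amyloid rule table covers only the printed
  cutoffs.
* Intercept intervals of Passing–Bablok are slightly anti-conservative
  at n ≈ 35 (≈90% empirical coverage at nominal 95%), a known property
  of the rank-based approximation.
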