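# plasmapanel

Blood-based biomarkers are the most scalable route to a timely biological
dementia diagnosis in the memory clinic. **plasmapanel** implements the full
development–validation–interpretation workflow for a multimarker plasma
panel — P-tau181, GFAP, NfL and the Abeta42/40 ratio — aimed at six clinical
contrasts: amyloid positivity in the whole clinic population and in the
pre-dementia (SCD/MCI) stages, and the differential contrasts AD vs FTD,
controls vs FTD, AD vs DLB, and controls vs DLB.

The package is for biostatisticians and clinical-chemistry groups who want
to develop or transport such panels: it handles the plumbing (cohort
schemas, amyloid-status adjudication from CSF/PET cutoffs, assay-lot
harmonization) and the statistics (penalized marker selection, diagnostic
models, thresholds, external validation, patient-level interpretation
graphics), with a synthetic cohort generator so everything runs without
patient-level data.

## The model

For a clinical question with binary outcome $y_i$ and marker vector
$x_i$ (raw concentrations), the diagnostic model is a logistic regression

$$\Pr(y_i = 1 \mid x_i) = \operatorname{logit}^{-1}(\beta_0 + \beta^\top x_i)$$

fit on markers chosen by bootstrapped LASSO: the L1 penalty $\alpha$ is
tuned by 10-fold cross-validated MSE of a penalized *linear* regression of
the 0/1 outcome on standardized markers, the selection is repeated over
1000 bootstrap resamples, and a marker enters the shared panel iff it is
selected in 100% of iterations for at least one question.

Interpretation uses three probability thresholds computed on the
development data: the Youden cutoff ($\max\ \text{sens} + \text{spec} - 1$),
the 90%-sensitivity cutoff $t_{sens}$ (largest cutoff with sensitivity
$\ge 0.90$) and the 90%-specificity cutoff $t_{spec}$ (smallest cutoff with
specificity $\ge 0.90$), defining *low* ($p \le t_{sens}$), *indeterminate*
and *high* ($p \ge t_{spec}$) likelihood zones. Per-marker Youden cutoffs
flag each marker normal/abnormal for UpSet-style summaries. External
transport of a frozen model is judged by a cohort-membership (case-mix)
model, discrimination at the development cutoff, calibration-in-the-large,
calibration slope and a Loess calibration curve. Assay-lot differences are
aligned with Passing–Bablok regression (shifted median of pairwise slopes).

## Worked example

```r
library(plasmapanel)

co <- simulate_cohort(seed = 7)         # 1199 subjects, 7 strata
m  <- fit_question_model(co, "Q2")      # amyloid status in SCD + MCI
summary(m)
#> Diagnostic question model: Q2_abeta_predementia
#>   markers: P-tau181, GFAP, NfL (age-corr.)
#>   n = 606 (0 dropped for missing markers)
#>   CV-AUC: 0.817 [0.783, 0.850] (10-fold)
#>
#> Logistic coefficients (log-odds per unit):
#>       (Intercept)           ptau181              gfap nfl_age_corrected
#>          -3.65559           0.57352           0.01949           0.02380
#>
#> Per-marker Youden thresholds:
#>             marker    cutoff       direction sensitivity specificity
#>            ptau181  1.507602 higher_abnormal   0.7965368   0.6106667
#>               gfap 73.375418 higher_abnormal   0.7878788   0.6586667
#>  nfl_age_corrected 12.059317 higher_abnormal   0.7316017   0.6240000
#>
#> Probability thresholds: youden 0.310 | sens90 0.229 | spec90 0.616
```

The CV-AUC is the pooled out-of-fold area under the ROC curve with a
DeLong 95% interval; coefficients are per pg/mL (per unit ratio for
Abeta42/40), so the serialized model file is directly usable on raw assay
results. A new patient is interpreted against the model:

```r
classify_patient(m, list(ptau181 = 4.15, gfap = 106, nfl = 21.8), age = 65)
#> Patient result (Q2_abeta_predementia)
#>   probability: 0.787 -> high likelihood
#>   P-tau181              4.150  ABNORMAL
#>   GFAP                106.000  ABNORMAL
#>   NfL (age-corr.)      21.800  ABNORMAL
```

and a frozen model transports to a second cohort:

```r
val <- simulate_cohort(seed = 8, name = "validation")
validate_model(m, val)
#> External validation (Q2_abeta_predementia)
#>   AUC 0.860 [0.831, 0.890] on n = 606
#>   at dev cutoff 0.310: accuracy 0.751, sens 0.823, spec 0.707
#>   calibration-in-the-large -0.014 (perfect 0), slope 1.211 (perfect 1)
```

`patient_report()` renders the composite clinical interface (threshold
table, UpSet plot with the patient's combination boxed, density plot with
the patient's probability line); see `vignette("panel-development")` for
the methods behind every step.

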