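# pamet — phenotype-aligned metabolomics

Longitudinal biomarker cohorts are usually sampled on fixed calendar days,
but the biology that precedes an acute clinical event is locked to the
*event*, not to the calendar. When a complication such as delayed cerebral
ischemia (DCI) after aneurysmal subarachnoid hemorrhage (aSAH) strikes
different patients on different days, a fixed-day contrast mixes samples
that are hours, days, or an entire disease phase away from the event, and
event-locked metabolic signals are diluted away.

`pamet` implements the phenotype-aligned alternative for plasma
metabolomics (and any samples × features intensity table):

1. **Align** every sample of an event patient to that patient's own event
   time, `h = 24·t_event − 24·t_sample` hours pre-event, and stratify the
   case samples into half-open pre-event windows [24, 48) h and [48, 72) h.
2. **Match** k = 2 control samples (from never-event patients) to each case
   sample by day post-index-event plus a weighted Gower distance over age,
   sex, aneurysm location, Hunt–Hess and modified Fisher grades.
3. **Screen** every feature with Student's t, Welch's t and the
   Mann–Whitney U test on log₂ intensities, with Levene's (Brown–Forsythe)
   test as a heteroscedasticity trigger, Benjamini–Hochberg control across
   the scoped feature set (q < 0.05), per-test ranks, and log₂-space ratio
   features (e.g. Arg/Orn = log₂Arg − log₂Orn).
4. **QC** via PCA on Pareto-scaled data with Hotelling's T² exclusion at
   α = 0.001.
5. **Evaluate** a candidate predictor on one observation per patient
   (within-patient averaging, with a Monte Carlo single-sample sensitivity
   loop): standardized logistic regression (odds ratio per SD, McFadden
   pseudo-R², AIC), ROC with stratified-bootstrap CIs (2,000 replicates),
   DeLong's paired AUC test, and Spearman correlations with ordinal
   outcome scales (GOS, mRS).
6. **Compare designs**: the same feature screened per fixed calendar day,
   to quantify how much the alignment sharpened the signal.

A synthetic-cohort generator (`generateCohort()`, frozen study-scale
settings in `canonicalStudyConfig()`) reproduces the design quantities of
an aSAH/DCI cohort — 60 patients (half with the event), event day median 5
(IQR 4–5), every-other-day sampling over 7 days, 2,022 annotated features,
and an event-locked spike of −0.715 log₂ units (a 39 % depletion) confined
to the 24–48 h pre-event window — so every stage is testable without any
patient data.

## Worked example

```r
library(pamet)

cfg     <- canonicalStudyConfig(seed = 1)
gen     <- generateCohort(cfg)           # raw peak areas + spike truth
cohort  <- log2Transform(gen$cohort)
cohort
#> MetaboCohort: 2022 features x 240 samples
#>   patients: 60 ( 30 with event )
#>   assay state: log2
#>   annotated features: 2022

aligned <- alignToEvent(cohort)
strata  <- buildStrata(aligned, cohort)
strata$W24_48
#> WindowStratum W24_48 : 13 case samples, 120 pool controls

mt  <- selectMatchedControls(strata$W24_48, cohort)
res <- runDiscovery(cohort, strata$W24_48, mt$matches)
res[res$feature_id == "ARG", c("log2_fc", "p_student", "p_welch",
                               "p_mwu", "q", "rank_student")]
#>     log2_fc    p_student      p_welch        p_mwu           q rank_student
#>  -0.8001114 3.236939e-06 1.984158e-06 9.208494e-06 0.006545091            1
```

The planted arginine-like feature is recovered as the top-ranked feature
of all 2,022 with an estimated depletion of 0.80 log₂ units (42.6 %,
truth −0.715 / 39 %) and FDR significance q = 0.0065 in the 24–48 h
window. Evaluating it as a patient-level predictor:

```r
obs <- buildPatientObservations(cohort, strata$W24_48, mt$matches, "ARG")
fitLogisticStandardized(obs, "ARG", "predictor_only")
#> Logistic model [predictor_only]
#>   term coefficient odds_ratio or_ci_low or_ci_high       p
#> 1  ARG       -2.54     0.0792    0.0154      0.409 0.00246
#>   McFadden pseudo-R2: 0.487  AIC: 25.08  AUC: 0.928
```

Lower arginine predicts the event (odds ratio < 1 per SD), and the
predictor separates patients with AUC 0.93 on this simulated cohort.
`runPipeline(runConfig(synthetic = cfg, seed = 1, out_dir = "out"))` runs
all stages end to end and writes every result table plus a JSON manifest;
`inst/scripts/pam.R` exposes the same runs from a shell.

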