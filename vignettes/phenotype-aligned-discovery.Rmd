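---
title: "Phenotype-aligned discovery: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-aligned discovery: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamet)
```

# The problem and the model

In a longitudinal cohort where an acute complication (here: delayed
cerebral ischemia, DCI, after aneurysmal subarachnoid hemorrhage) strikes
different patients on different days, a case–control contrast at a fixed
calendar day compares metabolic states that are heterogeneous in their
distance to the event. The phenotype-aligned design replaces the calendar
axis with an event-anchored axis: each sample of an event patient is
expressed as hours before that patient's own event, and only samples in a
narrow pre-event window are contrasted against day-matched control
samples. The package implements this retrospectively — event times must be
known — and for single-event patients only.

## Alignment and windows

At day resolution `hours_pre_event = (event_day − day_post_index) × 24`;
when an `hour_post_index` timestamp is available it takes precedence
(`event_day × 24 − hour_post_index`). Windows are half-open:
`W24_48 = [24, 48)` and `W48_72 = [48, 72)` hours pre-event. The interval
[0, 24) is deliberately excluded — a marker that only moves in the final
hours before diagnosis has little actionable lead time — and samples at or
after the event stay in the data model but never enter a stratum. At
whole-day resolution the windows collapse to "one day before" and "two
days before", so the boundary ownership (which end is closed) only matters
for hour-resolution data; we fixed lower-closed/upper-open once and use it
everywhere.

## Matched controls

Each case sample receives `k = 2` control samples from never-event
patients, restricted to the same collection day (tolerance 0, widened to
±1 day only when the same-day pool is smaller than k) and ranked by a
weighted Gower-style distance

```
d = |Δage|/IQR_age + 1[sex differs] + 1[location differs] + |ΔHH|/4 + |ΔmF|/4 ,
```

with unit weights by default. The source study names the matching
variables but not the metric, weights, tie-breaking, or reuse rules, so
these are package design choices, fixed in `matchConfig()` and echoed in
every run manifest: ties break deterministically by (distance, control
patient id, control sample id); a control sample may serve several cases
(`per_case_unique`), which reproduces the many-cases-few-controls
structure of sample-level matching in a small cohort (in our simulations
~22 distinct controls back ~30 case slots per window, a reuse rate close
to the study's 53 distinct samples for 72 slots); `globally_unique` is
available for sensitivity analyses. Greedy per-case selection is exactly
optimal when reuse is allowed, which the test suite verifies by brute
force on small pools.

## The differential screen

All testing happens on log₂ peak areas (zeros are floored to half the
smallest positive value of the same feature before the transform; the
floor is configurable and can be disabled). Per feature the screen
reports Student's t (the primary p-value feeding BH correction, matching
the volcano-plot convention), Welch's t and the Mann–Whitney U test, plus
Levene's variance test. Choices worth spelling out:

* **Levene center**: median (the Brown–Forsythe variant), because it is
  the robust default; mean centering is available. A Levene p < 0.1
  raises `robustness_flagged`, signaling that the variance-robust tests
  deserve equal attention.
* **Mann–Whitney**: exact null distribution (via the Wilcoxon count
  distribution, equivalent to enumerating all labelings) when both groups
  have ≤ 25 observations and no ties; otherwise the normal approximation
  with tie and continuity correction.
* **Degenerate features** (zero pooled variance) are reported with `NA`
  p-values and excluded from the FDR burden.
* **BH scope**: `annotated_only` vs `all_features` reproduces the two
  multiple-testing burdens of an annotated-only versus full-matrix
  screen; ratio features are corrected across the ratio set only (m =
  number of ratios), since they form a separate hypothesis family.
* **Ranks**: ascending-p with ties sharing the minimum rank; the
  cross-method concordance table flags features that are top-k under
  every test.

The paired signed-rank test for patients observed in both windows is
exact: after dropping zero differences (Wilcoxon's convention) the null
distribution of the positive-rank sum is built by convolution over the
(possibly tied, average) ranks, which enumerates all 2^n sign
assignments; two-sided p is the null mass of deviations from E[W] at
least as extreme. This is exercised on constructed difference sets in the
tests, because under a strict every-other-day grid each simulated event
patient contributes exactly one sample to exactly one window — dual-window
patients arise only from irregular real-world sampling.

## QC

PCA runs on Pareto-scaled log₂ data (per feature: center, divide by the
square root of the SD — the metabolomics compromise that keeps
high-intensity features from dominating without amplifying noise the way
unit-variance scaling does). Hotelling's T² over the first A = 5
component scores is compared against `A(n−1)/(n−A) · F(1−α; A, n−A)` at
α = 0.001, and samples above the threshold are excluded once (no
iterative re-screening). Both A and α are exposed because reasonable
studies differ here; five components echo the variance summary
convention for untargeted data.

## Clinical evaluation

Regression needs independent observations, so samples collapse to one row
per patient: case patients contribute their in-window sample (if two, the
one closest to 24 h pre-event — the most actionable state), control
patients the average of their matched samples. The averaging choice is
audited by the Monte Carlo loop (default 1,000 iterations) that redraws
one random sample per control patient and refits the model. Logistic
models use predictors z-scored on the analysis set after averaging (the
order is a package decision; standardizing before averaging would mix
sample- and patient-level scales), and report odds ratios per SD with
Wald CIs, McFadden pseudo-R² `1 − ll_model/ll_null`, and AIC. Possible
separation is flagged, never silently reported.

ROC analysis uses the rank (Mann–Whitney) AUC with ties counting one
half; CIs come from outcome-stratified bootstrap (percentile by default,
`basic` available) with 2,000 replicates. Because the ROC score is the
model's fitted event probability, protective predictors (negative
coefficients) still land above 0.5. DeLong's test is implemented from
placement values (structural components), which makes the single-AUC
variance testable against the bootstrap and the whole implementation
testable against an independent reference; both checks are in the suite.
Spearman correlations with ordinal outcomes use average ranks and the
t approximation on pairwise-complete pairs (n ≥ 5), since not every
patient has 12-month follow-up.

# The synthetic cohort generator

`generateCohort()` emulates the study design, not its raw data: 60
patients, half with the event; event day drawn from
`{3: 0.10, 4: 0.30, 5: 0.40, 6: 0.10, 7: 0.10}`, which realizes the
reported median 5 and IQR 4–5 (verified by Monte Carlo in the tests);
every-other-day sampling over 7 days with a random per-patient phase so
both windows populate; severity grades drawn from event-conditional
distributions so event patients skew higher (echoing the admission-grade
imbalance that matching must correct); outcome scales likewise
event-conditional. Features are independent Gaussians in log₂ space with
per-feature baselines μ_f ∈ [20, 30] and σ_f ∈ [0.3, 0.9] (the intensity
and dispersion range of plasma untargeted data); the cohort is stored as
raw areas `2^x` so the on-disk contract (non-negative peak areas) and the
log₂ code path are both exercised. Spikes shift the samples of event
patients that fall in a spike window by the window's log₂ effect; the
canonical set plants −0.715 at 24–48 h (the arginine-like marker, a 39 %
depletion), −0.38 (citrulline-like), −0.35/−0.31 across both windows
(glutamine-like), and two null anchors for the ratio analysis.

What the generator does **not** model: feature–feature correlation
(a block-correlation knob would be the natural extension), within-patient
autocorrelation, missingness, batch effects, or instrument drift. Passing
tests therefore demonstrate that the machinery recovers event-locked
effects under clean noise at study scale — not that any particular real
metabolite behaves this way.

## Power at study scale, honestly

Across 200 simulated study-scale cohorts the spike's estimated log₂ fold
change is unbiased (mean within ±0.1 of −0.715) and the 48–72 h screen is
clean, but FDR significance of the spike in any single 24–48 h replicate
is itself stochastic: with Δ = 0.715, noise σ in the configured range and
~15 case vs ~22 distinct control samples, the Student p concentrates
around 10⁻⁴, while BH at m = 2,022 demands p below ~2.5 × 10⁻⁵. A single
cohort can land on either side (the worked example lands at q = 0.0065;
other seeds land at q ≈ 0.2), and simulations put the q < 0.05 fraction
near one third. This is a property of the design's sample sizes, not of
the implementation — worth keeping in mind when a single-cohort q-value
near the threshold is interpreted.

# Problem sizes and runtime choices

The test suite runs the full recovery simulation at study scale (200
cohorts × 2,022 features; the screen is vectorized over features so this
stays in the minutes range), type-I simulations on 500-feature zero-spike
cohorts, and design-comparison simulations on 200-feature cohorts (the
tracked feature's p-value does not depend on how many null features sit
beside it). Bootstrap sizes default to 2,000 replicates; the null-coverage
simulation in the tests uses 500 per repetition to keep the loop cheap
without changing what is being checked.

# Known limitations

Retrospective alignment only; day-resolution alignment inherits ±12 h
window blur unless timestamps are supplied; single-event patients;
matching has no caliper by default (configurable) and does not implement
propensity or optimal-network matching; the fixed-timepoint comparator
uses the same test machinery, so design comparisons are internally
consistent but share any of its assumptions.
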