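---
title: "Methods: the GERtality score, its development procedure, and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the GERtality score, its development procedure, and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gertality)
```

## The clinical problem

Geriatric trauma patients (65 years and older) die in hospital far more
often than younger patients with comparable injuries, and the established
trauma prognosis models are either not tailored to this group or too
complex to compute at the bedside. The GERtality score addresses this with
five dichotomous findings, each worth one point when present:

1. age ≥ 80 years,
2. maximum AIS (Abbreviated Injury Scale) in any body region ≥ 4,
3. packed red-blood-cell transfusion before ICU admission,
4. pre-injury ASA physical status ≥ 3,
5. GCS (Glasgow Coma Scale) ≤ 13.

The total therefore ranges from 0 to 5, with observed in-hospital
mortality rising steeply across the levels. For comparison the package
also computes the Geriatric Trauma Outcome Score,
GTOS = age + 2.5 × ISS + 22 × [transfused], the Injury Severity Score
(ISS: sum of squares of the three highest regional AIS grades, 75 if any
region is graded 6), and the maximum AIS.

The GCS criterion appears in three equivalent phrasings in the published
materials on the score — "GCS ≤ 13", "GCS < 14", and the band "3–13" — and
is implemented as `gcs <= 13`. The ASA criterion is `asa >= 3` (band
"3/4").

## Cohort model and inclusion filter

A cohort couples the included patient records with an exclusion log so
counts are conserved: every input record lands either in the records or in
the log, and filtering an already-filtered cohort removes nothing. The
filter keeps patients aged ≥ 65, treated in a European hospital, primarily
admitted (no transfer in or early transfer out), with known pre-ICU
transfusion status, and with either relevant trauma (maximum AIS ≥ 3) or
minor trauma that nonetheless required intensive care.

Two policies here were genuinely open and are fixed as follows:

* **Exclusion-reason precedence.** When several rules fire, the logged
  reason is the first in the order under-65, non-European, transfer,
  missing transfusion data, minor trauma without ICU. This makes the
  exclusion log deterministic.
* **Missingness.** A missing transfusion flag excludes the record (that
  variable defines both a score criterion and a GTOS term), whereas
  missing GCS or ASA does not: registries of this kind tolerate missing
  values in those fields, and per-variable evaluable counts differ row by
  row in published screening tables. Score-level handling of missing
  GCS/ASA is then controlled by an explicit `missing_policy`:
  `zero_points` (default — a bedside score must be computable with partial
  data; unknown criteria contribute 0) or `propagate_missing` (the total
  becomes `NA`, for complete-case analyses).

The six-region AIS scheme (head/neck, face, chest, abdomen, extremities
including pelvis, external) is used because the ISS is defined over
exactly those regions; AIS severities are taken as given integers 0–6 and
no coding-to-severity mapping is attempted.

## The development procedure

Score development mimics how such additive scores are derived from a
registry:

1. **Dichotomization.** Continuous candidates are dichotomized by
   searching a cut-off grid for the least extreme cut-off whose exposed
   group reaches a target mortality (`target_mortality`, default 0.30;
   descriptions of this style of development quote both "at least 25%" and
   "approximately 30% or more", so the target is a parameter documented
   with both values). "Least extreme" is the cut-off exposing the most
   patients. The default grids are age {65, 70, 75, 80, 85}, maximum AIS
   {3, 4, 5}, ASA {2, 3} and GCS upper bounds {8, 12, 13} — a documented
   choice, since the exact grids searched in the original development are
   not published. Inherently binary candidates (transfusion, male sex,
   high-energy mechanism, systolic blood pressure ≤ 90 mmHg) keep their
   fixed dichotomy.
2. **Odds-ratio screening.** Each dichotomy gets a 2×2 mortality table and
   an odds ratio. Records with missing predictor values are excluded per
   variable and the dropped count is always reported.
3. **Selection.** Candidates with OR strictly greater than `or_threshold`
   (default 2.0) are assembled, in a fixed canonical order, into a
   one-point-per-criterion score definition.

Both a `univariable` mode (the default: published screening tables of this
kind print univariable ORs) and a `multivariable` mode (ORs from a joint
logistic model over all dichotomized candidates) are provided, because the
two descriptions of the original procedure disagree on which was used; the
package exposes both rather than resolving the discrepancy.

Applying the selection rule to the published screening statistics of the
original development cohort (shipped as
`gertality_development_reference()`: ORs 2.27, 6.25, 2.99, 2.09, 7.61)
reproduces the five-criterion GERtality definition exactly, and
reconstructing each 2×2 table from the published subgroup sizes and
one-decimal mortality rates reproduces the published ORs to within ±0.1
(the residual is entirely due to the rate rounding; e.g. the GCS row
recomputes as 7.57 against a published 7.61).

### Numerical choices

* Odds ratios are crude cross-product ratios; whether the published values
  were continuity-corrected or model-based is not stated, and the crude OR
  matches them within rate-rounding. The Wald CI uses z = 1.96 on the log
  scale with SE = sqrt(1/a + 1/b + 1/c + 1/d). A Haldane–Anscombe
  correction (`continuity = 0.5`) is available; with the default k = 0 a
  zero cell yields an infinite or zero OR with an undefined CI, flagged
  rather than silently dropped.
* The logistic model is fitted by iteratively reweighted least squares via
  `stats::glm` (up to 100 iterations, tight convergence tolerance).
  Separation and divergence raise diagnostic errors instead of returning a
  silent result; a fit is also rejected when any coefficient exceeds 30 in
  absolute value.

## Evaluation

`mortality_by_score()` tabulates observed mortality per score level 0–5
with exact (Clopper–Pearson) binomial intervals; empty levels are reported
with n = 0 and missing scores are counted, not hidden.

`roc_auc()` computes the AUC by the Mann–Whitney statistic with ties
counted one half — essential here because the GERtality score takes only
six values — and builds the ROC polygon from a threshold at every distinct
score. With midrank tie handling, the trapezoidal area under that polygon
equals the Mann–Whitney AUC exactly, which the tests verify to 1e-12
against a brute-force pair-counting oracle. Confidence intervals use
DeLong's placement-value variance by default (appropriate at registry-scale
n; the package cross-checks both the AUC and the interval against pROC) or
a stratified bootstrap as a fallback for small samples. Orientation is
fixed: a higher score predicts death, and an anti-discriminating score
reports AUC < 0.5 rather than being auto-flipped. `compare_scores()`
computes all requested AUCs on the intersection of records where every
score is evaluable, so the comparison is on identical subsets (the policy
used in the original analysis is not stated; the intersection is the
conservative choice).

No statistical test for paired AUC differences and no calibration-slope
modelling are provided, and the AUC values published for the original
registry cohort (e.g. 0.803 for GERtality, 0.784 for GTOS, 0.879 for the
15-variable registry model) are not reproducible without access to that
restricted registry; the package's claims about its own evaluation
machinery are therefore property-based, on synthetic cohorts.

## The synthetic registry generator

`generate_cohort()` emulates the structure of a large European geriatric
trauma registry cohort, not any individual patient data:

* age from a truncated normal (mean 77, SD 7.6, floor 65 years), implying
  P(age ≥ 80) ≈ 0.37;
* maximum-AIS level distribution with 45% mass at ≥ 4, regional profiles
  built around the maximum with the head/neck region carrying it most
  often (so severe head injury prevalence is realistic and ISS/max-AIS are
  internally consistent);
* prevalences 8% transfusion, 41% ASA ≥ 3, 41% GCS ≤ 13, 57.8% male; a
  mechanism mix dominated by low falls (45%) and traffic (35.1%);
  missingness rates of 4.8% for GCS and 16.5% for ASA, matching the
  per-variable evaluable-count differences seen in registry screening
  tables;
* a Gaussian copula with equicorrelation 0.2 linking injury severity, GCS
  depression and transfusion — the marginals are known but the joint
  distribution is not, so the correlation is a free parameter chosen so
  that univariable ORs stay near their targets;
* death drawn from a logistic model on the five binary risk indicators
  whose default coefficients are the logs of the published univariable ORs
  (2.27, 6.25, 2.99, 2.09, 7.61), with the intercept calibrated by
  bisection so expected overall mortality is 22.3%.

Using univariable ORs as conditional log-odds is a stated approximation,
not a claim about the real registry. Its visible consequence is logistic
non-collapsibility: marginal (univariable) ORs measured on the synthetic
cohort are attenuated relative to exp(β) for components independent of the
rest (age ≈ 1.9, ASA ≈ 1.6) and slightly inflated for the copula-linked
ones. Two things follow. First, the generator's subgroup mortalities
approximate but do not exactly match the published Table-style rates.
Second, running the full development procedure on the default synthetic
cohort selects the three strongest criteria (maximum AIS, transfusion,
GCS) rather than all five — an honest property of the simulated world, not
a defect of the selection operation, which recovers the five-criterion
definition exactly when given the published screening statistics. The
generator's defaults are study conditions, not tuning knobs.

All randomness flows from a single seed, so identical configuration and
seed give byte-identical cohorts. What passing tests on synthetic cohorts
do **not** show: anything about coding quality, hospital-level clustering,
length-of-stay dynamics, or the true conditional effect sizes in any real
registry.

## Problem sizes and test design

The package's simulation-based checks use cohorts of n = 50,000 (marginal
fidelity within 3 Monte-Carlo standard errors; strict monotonicity of
mortality across score levels; coefficient recovery within 3 standard
errors; transfusion OR within 25% of its target), n = 58,055 for the
overall-mortality calibration check (±1 percentage point), 2,000 simulated
2×2 tables at 1,000 per arm for Wald-CI coverage (expected in 93–97%), and
1,000 null replicates at 2,000 per class for DeLong-interval coverage of
AUC = 0.5. These sizes were chosen so each check's Monte-Carlo error is
small relative to its tolerance.

## Known limitations

* The developed score is not internally validated (no bootstrap or
  split-sample validation) — deliberately out of scope, as is any
  reimplementation of the 15-variable registry comparator model.
* GTOS is computed only up to the score value; the original logistic
  mapping from GTOS to a mortality probability uses coefficients not
  available here.
* Whether "transfusion before ICU" includes pre-hospital transfusion is
  registry-specific; the package treats it as a single upstream boolean.
* The synthetic generator reproduces marginals and a plausible dependence
  structure, not a real joint distribution.
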