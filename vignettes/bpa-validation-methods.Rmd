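---
title: "Methods: validating an ED diabetes-screening alert against chart review"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating an ED diabetes-screening alert against chart review}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpascreen)
```

## The problem

Emergency departments see many patients at elevated diabetes risk who are
unlikely to be screened in primary care. A best-practice advisory (BPA) built
into the EHR can flag, at the moment a routine lab is ordered, patients who
are eligible for HbA1c testing. Whether such an alert is *accurate* — firing
when it should and staying silent when it should not — has to be established
against a reference standard: manual review of the full chart.

This package implements that validation as a reusable, fully testable
pipeline. Because real patient-visit data cannot ship with software, it
includes a synthetic EHR cohort generator whose discordance structure
(structured record versus full chart) is controllable and can be calibrated
so that the *expected* confusion table matches any attainable target.

## The screening rule

A visit is eligible for HbA1c screening when

1. age ≥ 45 years, **or** age ≥ 18 with BMI ≥ 25 kg/m²; **and**
2. no history of diabetes or prediabetes; **and**
3. no HbA1c result in the three years before the visit;

and the advisory only fires when a routine lab order exists to attach the
HbA1c test to. All threshold comparisons are inclusive (≥), following the
wording of the rule. If the visit BMI is missing, the engine falls back to
the most recent BMI on file; if no BMI is available anywhere in the
structured record, the BMI criterion is unevaluable.

Two readings are possible for that last case: the age-alone criterion can
still fire (our default, `missing_bmi_suppresses_all = FALSE`), or the
advisory is suppressed entirely (`TRUE`). The rule's description supports
either reading; we default to the more permissive one because criterion 1
needs no BMI at all, and expose the strict reading as a configuration switch
for sensitivity analyses. The three-year lookback is consumed as a
precomputed boolean; when preparing real data we recommend a half-open
window of `3 * 365.25` days ending at the visit date, since the calendar
convention is otherwise ambiguous.

The engine is a pure function of the *structured* view: it cannot see free
text, scanned documents, or records shared from other institutions.

## The reference standard

Chart reviewers can see strictly more than the algorithm: chart-level
history flags (covering notes, scanned documents and the external-network
record) are modelled as supersets of the structured flags. The reference
label applies the same eligibility rule with the chart-level history flags
substituted for the structured ones, plus one addition: patients in whom
HbA1c is unreliable for diagnosis — pregnancy, sickle-cell anemia, HIV —
should never be flagged. An alert on such a visit counts against the
algorithm (a false positive). The converse completion is an interpretive
choice we make explicit: when the advisory correctly stays silent on such a
patient, the visit counts as a true negative, because the patient was not
eligible and no alert fired.

**BMI visibility.** The reviewers in the validation we model verified the
algorithm's BMI input against the BMI actually taken during the ED visit.
We therefore give the reference standard chart-level visibility of that
measurement (`chart_bmi`), while the engine sees only the structured fields.
This is the package's one deliberate asymmetry beyond the history flags,
and it is what makes false negatives possible at all: with superset history
flags and identical BMI visibility, a silent alert could never be wrong —
a structured diabetes flag implies a chart diabetes flag, so the reference
would agree with every suppression. Routing false negatives through the
missing-BMI channel also makes every one of them attributable: each FN
carries a `suppressed_missing_bmi` (or `suppressed_missing_age` /
`suppressed_no_lab`) reason code, mirroring how silent-alert errors arise in
practice (the algorithm's input was missing, not its logic wrong).

A consequence worth being honest about: the chart flags being supersets
means the model attributes *all* false negatives to missing BMI inputs. Real
EHRs also contain outright structured errors (e.g. a miscoded diagnosis)
that chart review overturns in the other direction; the generator does not
model those, and calibration to a 2×2 with a large FN cell therefore implies
a large structured-BMI missingness probability (≈ 0.95 per channel for the
published table). That is a modelling artifact of the chosen discordance
structure, not a claim about any real EHR's data quality.

## The generative model and its closed-form confusion table

Each visit draws, independently: a race/ethnicity stratum, sex, insurance, a
lab-order indicator, age (truncated normal, mean 48, SD 17.9, ≥ 18 years,
recorded in whole years), BMI (truncated normal, mean 30.1, SD 8.8,
≥ 12 kg/m², recorded to one decimal), visit-BMI missingness, historical-BMI
availability, structured and chart-only diabetes-history flags, structured
and chart-only HbA1c flags, and an HbA1c-unreliability condition. A single
seeded RNG stream feeds these fields in a fixed, documented order, so a
cohort is byte-reproducible from its parameters. Truncated normals are the
minimal assumption when only a mean and SD are available; the truncation
points are the adult age floor and a physiologic BMI floor.

Writing $a = P(\text{age} \ge 45)$, $b = P(\text{BMI} \ge 25)$ (computed at
44.5 years and 24.95 kg/m² on the continuous scale to respect the recording
granularity), $m$ = probability both structured BMI fields are blank, $s$ =
probability of a clean structured history, $c$ = probability the chart adds
nothing beyond the structured record, and $x$ = probability of no
exclusion condition, the expected cells of the lab-ordered cohort are

$$P_{\mathrm{eng}} = a + (1-a)\,b\,(1-m), \qquad
  P_{\mathrm{fn}} = (1-a)\,b\,m,$$

$$TP = P_{\mathrm{eng}}\, s\, c\, x,\quad
  FP = P_{\mathrm{eng}}\, s\, (1 - c\,x),\quad
  FN = P_{\mathrm{fn}}\, s\, c\, x,\quad
  TN = 1 - TP - FP - FN.$$

`expected_cells()` computes this map; a 512-path enumeration of the joint
outcome tree and a 100,000-visit simulation both confirm it in the test
suite. `calibrate_to_cells()` inverts it: given target cells, it solves

$$c\,x = \frac{TP}{TP+FP}, \qquad
  m = \frac{r\,(a+(1-a)b)}{(1+r)(1-a)b} \text{ with } r = \frac{FN}{TP},
  \qquad s = \frac{TP+FP}{a+(1-a)b(1-m)},$$

splitting each joint probability evenly across its two constituent channels
(any split with the same product gives the same expected cells). Targets
that exceed the model's capacity — an FN/TP ratio larger than the
missing-BMI channel can carry, an alert rate above the demographic
eligibility, an exclusion probability already above the demanded
false-positive share — raise calibration errors rather than silently
clamping.

## Verification sampling and weights

Verifying every silent alert by chart review is expensive, so the design
verifies all alert-positive visits and a stratified 10% of the negatives
(by race/ethnicity), without replacement, with half-up rounding of each
stratum's sample size. Each sampled negative carries the Horvitz–Thompson
weight $N_h / n_h$ (stratum negatives over stratum sample size), so the
weights of a stratum's sample sum *exactly* to its population size and the
weighted 2×2 is design-unbiased for the census 2×2 — a property the test
suite checks over 200 replicate draws. A stratum whose sample would round
to zero is a design error, not a silent omission.

## Accuracy statistics

From the (possibly weighted) table: sensitivity $TP/(TP+FN)$, specificity
$TN/(TN+FP)$, PPV $TP/(TP+FP)$, NPV $TN/(TN+FN)$, each with the binomial
standard error $\sqrt{p(1-p)/n}$ over its own denominator and a
natural-scale Wald interval truncated to $[0,1]$. Likelihood ratios
$LR^+ = \mathrm{sens}/(1-\mathrm{spec})$ and
$LR^- = (1-\mathrm{sens})/\mathrm{spec}$ use the delta method on the log
scale,

$$\mathrm{Var}(\ln LR^+) = \frac{1-\mathrm{sens}}{\mathrm{sens}\; n_{pos}}
  + \frac{\mathrm{spec}}{(1-\mathrm{spec})\; n_{neg}},$$

back-transformed to a natural-scale SE ($SE = LR\sqrt{\mathrm{Var}}$) and a
symmetric natural-scale Wald interval. We default to the natural scale
because it is what validation reports that print an SE beside a symmetric
CI use; the asymmetric log-scale interval, which cannot cross zero, is
available via `ci_scale = "log"`. A bootstrap over 10,000 multinomial
resamples of the 2×2 agrees with the delta-method SEs within a few percent
in the test suite. Prevalence-based predictive values follow Bayes' rule
(`predictive_values_from_prevalence()`); with prevalence set to the sample
prevalence they reproduce the table's direct PPV/NPV to numerical
precision, which the tests assert at 1e-12.

Wald intervals on proportions are known to undercover near 0 and 1; for the
cell sizes this design targets (hundreds per margin) they are adequate, and
they are the convention of the reports this package is built to reproduce.
Weighted cells reuse the same formulas with weighted denominators, which
ignores the design-variance inflation of the sampled stratum — the same
simplification the reproduced analysis makes; the bootstrapped AUC interval
is unaffected.

**Acceptability rules** (all pre-specified, not data-driven): sensitivity
plus specificity at least 150%; $LR^+$ between 5 and 10 acceptable (above
10 strong); $LR^-$ between 0.1 and 0.2 acceptable, 0.2–0.5 still
informative for moving pre- to post-test probability, above 0.5 weak; AUC
in $[0.7, 0.8)$ acceptable and $\ge 0.8$ excellent, with boundaries
assigned to the upper band.

## The weighted ROC/AUC

The outcome is *correct adjudication*: the alert decision agreed with the
reference label. A weight-adjusted logistic regression models this outcome
on the four rule inputs — age and BMI continuous, the chart-level diabetes
and HbA1c history flags binary; the predictor coding is not uniquely
determined by the design we reproduce, and continuous age/BMI is the
default a modeller would choose first. We use the quasibinomial family
because Horvitz–Thompson weights are non-integer. The AUC is the weighted
concordance of the fitted scores (ties counted ½), computed in
O(n log n) and verified against an O(n²) pair loop to 1e-12. The interval
is a seeded percentile bootstrap (default 2,000 replicates) stratified on
the outcome so both classes persist in every resample; the bootstrap refits
the model each time. Complete separation is flagged, not fatal: the AUC of
a separating score is still well-defined.

## What the synthetic cohort does and does not show

The generator reproduces: the marginal demographics (age, BMI, sex,
race/ethnicity, insurance) of a one-month urban ED census; the lab-order
rate; and — after calibration — any attainable expected 2×2, hence the
operating point (sensitivity ≈ 0.69, specificity ≈ 0.91) of the validation
it emulates. Passing tests therefore show the *pipeline* is correct: the
rule is implemented as stated, the weights are design-unbiased, the
statistics match their closed forms and oracles.

It does not reproduce: correlations between fields (age–BMI, history–age,
exclusion–demographics are all independent here); longitudinal structure;
free text; structured-record errors that chart review overturns toward
eligibility; or the true joint distribution behind the published AUC, which
depends on how adjudication errors co-vary with age and BMI. The simulated
AUC (≈ 0.71–0.76 across seeds under the calibrated defaults) happens to
bracket the published 0.74, but only the 2×2-derived statistics are exactly
recoverable by construction.

## Problem sizes and numerical choices

The shipped analyses use: 3,850 simulated adults (≈ 2,963–3,030 lab-ordered)
for the study-scale replication; 50,000 lab-ordered visits for parameter
recovery (Monte-Carlo SE on sensitivity ≈ 0.004, so a 3-SE check is a ±0.01
band); 200 replicate draws for the sampling-unbiasedness check; 2,000
bootstrap replicates for AUC intervals in the analysis scripts. Reported
tables round half-up to two decimals. Ages are whole years and BMIs one
decimal, and the analytic cell formulas use the matching half-ulp-shifted
thresholds, so analytic and simulated cells agree without a continuity
fudge. Seeds are explicit everywhere randomness exists: cohort generation,
the negative-sample draw, and the AUC bootstrap.

## Known limitations

* All false negatives flow through missing structured inputs; a validation
  of an EHR whose silent-alert errors come from miscoded structured data
  would need an additional discordance channel that deliberately violates
  the chart-superset assumption.
* Wald and delta-method intervals are asymptotic; very small or very
  unbalanced tables should use the log-scale LR interval and treat the
  proportion CIs with caution.
* The weighted logistic AUC is validated by construction-level oracles and
  plausibility, not exact reproduction, because the original model's exact
  sample (weighted subsample versus extrapolated counts) is not
  reconstructible from the published information.
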