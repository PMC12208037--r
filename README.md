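# bpascreen

Validation toolkit for a rule-based **best-practice advisory (BPA)** that
flags emergency-department patients eligible for HbA1c diabetes screening —
plus a synthetic EHR cohort generator so the entire validation is
reproducible without patient data.

## The problem

EDs see many patients at high diabetes risk who are rarely screened in
primary care. An EHR alert can offer an HbA1c test whenever a routine lab is
already ordered and the patient meets screening criteria:

- age ≥ 45, **or** age ≥ 18 with BMI ≥ 25 kg/m²; and
- no recorded diabetes/prediabetes history; and
- no HbA1c result in the preceding 3 years.

The algorithm only sees the *structured* record. Chart reviewers see
strictly more — free text, scanned documents, external-network records, the
BMI actually measured at the visit — and they also flag patients in whom
HbA1c is unreliable (pregnancy, sickle-cell anemia, HIV); alerts on those
count against the algorithm. Validation means scoring the alert against that
chart-review reference standard.

## What the package computes

From a (possibly weighted) 2×2 of alerts vs. reference labels with cells
TP, FP, FN, TN:

- sensitivity TP/(TP+FN), specificity TN/(TN+FP), PPV TP/(TP+FP),
  NPV TN/(TN+FN), each with binomial SE √(p(1−p)/n) and Wald 95% CI;
- likelihood ratios LR⁺ = sens/(1−spec), LR⁻ = (1−sens)/spec with
  delta-method SEs on the log scale, Var(ln LR⁺) = (1−sens)/(sens·n₊) +
  spec/((1−spec)·n₋), back-transformed to natural-scale SE and CI;
- Bayes predictive values at any prevalence π:
  PPV = sens·π / (sens·π + (1−spec)(1−π));
- a weighted-logistic ROC/AUC of *correct adjudication* on the four rule
  inputs, with a seeded stratified bootstrap CI;
- pre-specified acceptability verdicts (sens+spec ≥ 150 %; LR⁺ in [5,10];
  LR⁻ in [0.1,0.2], 0.2–0.5 "informative"; AUC ≥ 0.7 acceptable, ≥ 0.8
  excellent).

Around this sit the rule engine (`evaluate_bpa()`), the chart-review
reference standard (`review_chart()`), stratified verification sampling of
the alert-negatives with Horvitz–Thompson weights (`sample_negatives()`),
and a synthetic cohort generator (`generate_cohort()`) whose expected 2×2
has a documented closed form (`expected_cells()`) and a closed-form inverse
(`calibrate_to_cells()`). See `vignette("bpa-validation-methods")`.

## Worked example

Test characteristics from a published chart-review 2×2 (599/197/265/1902):

```r
library(bpascreen)
ct <- confusion_table(tp = 599, fp = 197, fn = 265, tn = 1902)
print(accuracy_report(ct))
#> Diagnostic accuracy (CI level 95%)
#>   sensitivity   0.69  SE 0.02  CI (0.66 - 0.72)
#>   specificity   0.91  SE 0.01  CI (0.89 - 0.92)
#>   ppv           0.75  SE 0.02  CI (0.72 - 0.78)
#>   npv           0.88  SE 0.01  CI (0.86 - 0.89)
#>   lr_pos        7.39  SE 0.53  CI (6.35 - 8.42)
#>   lr_neg        0.34  SE 0.02  CI (0.30 - 0.37)
```

A sensitivity of 0.69 means the alert fires for 69 % of truly eligible
visits; LR⁺ = 7.39 means a fired alert multiplies the odds of true
eligibility by about 7.4. Both clear the pre-specified bars
(sens+spec = 1.60 ≥ 1.5; LR⁺ in [5, 10]), and LR⁻ = 0.34 sits in the
"informative" 0.2–0.5 band.

End-to-end on synthetic data — calibrate the generator to that table,
simulate a lab-ordered cohort, and re-estimate from scratch:

```r
params <- calibrate_to_cells(ct, cohort_params(n_patients = 50000,
                                               p_lab_ordered = 1, seed = 7))
cohort <- generate_cohort(params)
dec <- evaluate_bpa(cohort)
lab <- review_chart(cohort)
accuracy_metrics(build_confusion(dec, lab))
#> Diagnostic accuracy (CI level 95%)
#>   sensitivity   0.69  SE 0.00  CI (0.68 - 0.70)
#>   specificity   0.91  SE 0.00  CI (0.90 - 0.91)
#>   ppv           0.75  SE 0.00  CI (0.75 - 0.76)
#>   npv           0.88  SE 0.00  CI (0.87 - 0.88)
```

The recovered sensitivity/specificity (0.691/0.906 at this seed) match the
calibration target (0.693/0.906) to Monte-Carlo precision.

## The analysis workflow

Numbered drivers under `analysis/` replay the full study on synthetic data;
each prints what it found and writes small tables under `results/` (large
per-visit tables go to `scratch/`):

1. `01_simulate_cohort.R` — calibrate to the published 2×2, simulate 3,850
   adult visits (~77 % lab-ordered).
2. `02_run_algorithm.R` — rule engine + reference standard; alert cascade
   and suppression-reason counts.
3. `03_diagnostic_accuracy.R` — 10 % stratified verification sample,
   weighted 2×2, all test characteristics, weighted ROC/AUC, verdicts.
4. `04_reproduce_published_table.R` — test characteristics straight from
   the published counts (no simulation).

Run them in order with `Rscript analysis/01_simulate_cohort.R` etc.

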