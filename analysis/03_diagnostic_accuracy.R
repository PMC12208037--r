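#!/usr/bin/env Rscript
# Stage 3 — diagnostic accuracy under the verification-sampling design.
#
# All alert-positive visits are verified; a 10% stratified sample of the
# alert-negatives (by race/ethnicity) is verified and re-weighted to the
# cohort with Horvitz-Thompson weights. Computes the weighted 2x2, all test
# characteristics, the weighted-logistic ROC/AUC, and the pre-specified
# acceptability verdicts, and contrasts them with the census (all labels
# known) analysis that the synthetic cohort makes possible.
#
# Reads:  scratch/cohort.csv, scratch/decisions.csv, scratch/labels.csv
# Writes: results/validation_report.json, results/roc.csv

suppressMessages(library(bpascreen))
for (f in c("scratch/cohort.csv", "scratch/decisions.csv", "scratch/labels.csv")) {
  if (!file.exists(f)) stop("run analysis/01 and analysis/02 first")
}

cohort <- read_cohort_csv("scratch/cohort.csv")
analysis <- cohort[cohort$lab_ordered, ]
decisions <- utils::read.csv("scratch/decisions.csv", stringsAsFactors = FALSE)
labels <- utils::read.csv("scratch/labels.csv", stringsAsFactors = FALSE)

## verification-sample analysis (the study design)
ver <- sample_negatives(analysis, decisions, sampling_design(0.10, seed = 9))
tab <- attr(ver, "stratum_table")
cat(sprintf("verified %d alert-positives and %d of %d negatives (10%% per stratum)\n",
            sum(ver$triggered), sum(!ver$triggered), sum(tab$n_negative)))

ct_ver <- build_confusion(decisions, labels, ver[, c("visit_id", "weight")])
cat("\nweighted 2x2 (extrapolated to the cohort):\n")
print(ct_ver)

auc <- weighted_auc(analysis, decisions, labels, ver[, c("visit_id", "weight")],
                    n_boot = 2000, seed = 10)
report <- accuracy_report(ct_ver, auc = auc$metric)
cat("\n")
print(report)
verdicts <- acceptability(report)
cat(sprintf("\nsens+spec = %.2f (>=1.5: %s); LR+ band: %s; LR- band: %s; AUC band: %s\n",
            verdicts$sens_spec_sum, verdicts$sens_spec_ok,
            verdicts$lr_pos_band, verdicts$lr_neg_band, verdicts$auc_band))

## census analysis (every synthetic label known) for comparison
ct_census <- build_confusion(decisions, labels)
census <- accuracy_report(ct_census)
cat(sprintf("\ncensus check: sensitivity %.3f, specificity %.3f (weighted estimates %.3f, %.3f)\n",
            census$metrics$sensitivity$estimate,
            census$metrics$specificity$estimate,
            report$metrics$sensitivity$estimate,
            report$metrics$specificity$estimate))

jsonlite::write_json(
  list(confusion_weighted = unclass(ct_ver),
       confusion_census = unclass(ct_census),
       metrics = report$metrics,
       census_metrics = census$metrics,
       verdicts = verdicts),
  "results/validation_report.json", auto_unbox = TRUE, digits = 6)
utils::write.csv(auc$roc, "results/roc.csv", row.names = FALSE)
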