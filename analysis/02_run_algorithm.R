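#!/usr/bin/env Rscript
# Stage 2 — run the screening rule and the chart-review reference standard.
#
# The rule engine sees only the structured record; the reference standard
# sees the full chart (chart-level history flags, the visit BMI, and the
# HbA1c-unreliability conditions). Reports the alert cascade and the reasons
# alerts were suppressed.
#
# Reads:  scratch/cohort.csv              (from 01_simulate_cohort.R)
# Writes: scratch/decisions.csv, scratch/labels.csv, results/cascade.json

suppressMessages(library(bpascreen))
if (!file.exists("scratch/cohort.csv")) stop("run analysis/01_simulate_cohort.R first")

cohort <- read_cohort_csv("scratch/cohort.csv")
analysis <- cohort[cohort$lab_ordered, ]

decisions <- evaluate_bpa(analysis)
labels <- review_chart(analysis)
utils::write.csv(decisions, "scratch/decisions.csv", row.names = FALSE)
utils::write.csv(labels, "scratch/labels.csv", row.names = FALSE)

cascade <- c(adults = nrow(cohort),
             lab_ordered = nrow(analysis),
             bpa_triggered = sum(decisions$triggered),
             should_have_triggered = sum(labels$should_trigger))
cat(sprintf("cascade: %d adults -> %d lab ordered -> %d alerts (%.0f%%); reference says %d should fire\n",
            cascade[1], cascade[2], cascade[3],
            100 * cascade[3] / cascade[2], cascade[4]))

# suppression accounting, echoing per-reason counts
for (code in c("suppressed_missing_bmi", "suppressed_missing_age", "suppressed_no_lab")) {
  cat(sprintf("  %-24s %d visits\n", code,
              sum(grepl(code, decisions$reason_codes))))
}
jsonlite::write_json(as.list(cascade), "results/cascade.json",
                     auto_unbox = TRUE)
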