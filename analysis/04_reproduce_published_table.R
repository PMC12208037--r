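#!/usr/bin/env Rscript
# Stage 4 — test characteristics straight from the published 2x2.
#
# Independent of the simulation: takes the published chart-review counts
# (TP 599, FP 197, FN 265, TN 1902) as input and recomputes every test
# characteristic with its SE and 95% CI, plus the acceptability calculus
# (sens+spec >= 150%; minimum desired PPV/NPV at 30% prevalence assuming
# 75%/75% sensitivity and specificity).
#
# Writes: results/published_table_reproduction.csv

suppressMessages(library(bpascreen))
dir.create("results", showWarnings = FALSE)

ct <- confusion_table(tp = 599, fp = 197, fn = 265, tn = 1902)
rep <- accuracy_report(ct)
print(ct)
cat("\n")
print(rep)

pv <- predictive_values_from_prevalence(0.75, 0.75, 0.30)
cat(sprintf("\nminimum desired PPV/NPV at 30%% prevalence (75%%/75%%): %.0f%% / %.0f%%\n",
            round_half_up(100 * pv[["ppv"]]), round_half_up(100 * pv[["npv"]])))
v <- acceptability(rep)
cat(sprintf("sens+spec = %.2f (acceptable: %s); LR+ %s; LR- %s\n",
            v$sens_spec_sum, v$sens_spec_ok, v$lr_pos_band, v$lr_neg_band))

rows <- do.call(rbind, lapply(rep$metrics, function(m) {
  data.frame(metric = m$name,
             estimate = round_half_up(m$estimate, 2),
             se = round_half_up(m$se, 2),
             ci_low = round_half_up(m$ci_low, 2),
             ci_high = round_half_up(m$ci_high, 2))
}))
utils::write.csv(rows, "results/published_table_reproduction.csv",
                 row.names = FALSE)
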