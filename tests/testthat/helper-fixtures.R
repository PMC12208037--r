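# Shared fixtures and independent oracles.

# One-row visit record with sensible defaults; chart flags default to the
# structured flags (concordant record).
make_visit <- function(visit_id = "V1", age = 50,
                       visit_bmi = NA_real_, most_recent_bmi = NA_real_,
                       chart_bmi = NA_real_, lab_ordered = TRUE,
                       structured_diabetes_history = FALSE,
                       chart_diabetes_history = structured_diabetes_history,
                       structured_hba1c_within_3y = FALSE,
                       chart_hba1c_within_3y = structured_hba1c_within_3y,
                       exclusion_condition = "none",
                       race_ethnicity = "black_nh", sex = "female",
                       insurance = "medicaid") {
  data.frame(visit_id = visit_id, age = age, visit_bmi = visit_bmi,
             most_recent_bmi = most_recent_bmi, chart_bmi = chart_bmi,
             lab_ordered = lab_ordered,
             structured_diabetes_history = structured_diabetes_history,
             chart_diabetes_history = chart_diabetes_history,
             structured_hba1c_within_3y = structured_hba1c_within_3y,
             chart_hba1c_within_3y = chart_hba1c_within_3y,
             exclusion_condition = exclusion_condition,
             race_ethnicity = race_ethnicity, sex = sex,
             insurance = insurance, stringsAsFactors = FALSE)
}

# Independent brute-force evaluator of the screening rule, written as plain
# nested conditionals; deliberately shares no code with evaluate_bpa().
brute_force_bpa <- function(r, cfg = rule_config()) {
  if (cfg$require_lab_ordered && !isTRUE(r$lab_ordered)) return(FALSE)
  if (is.na(r$age)) return(FALSE)
  if (isTRUE(r$structured_diabetes_history)) return(FALSE)
  if (isTRUE(r$structured_hba1c_within_3y)) return(FALSE)
  bmi <- r$visit_bmi
  if (is.na(bmi)) bmi <- r$most_recent_bmi
  if (cfg$missing_bmi_suppresses_all && is.na(bmi)) return(FALSE)
  if (r$age >= cfg$age_threshold_alone) return(TRUE)
  if (!is.na(bmi) && r$age >= cfg$age_threshold_with_bmi &&
      bmi >= cfg$bmi_threshold) return(TRUE)
  FALSE
}

# O(n^2) weighted concordance oracle: explicit double loop over
# (positive, negative) pairs, ties counted one half.
concordance_pair_loop <- function(score, positive, weight) {
  num <- 0
  den <- 0
  for (i in which(positive)) {
    for (j in which(!positive)) {
      wij <- weight[i] * weight[j]
      den <- den + wij
      if (score[i] > score[j]) num <- num + wij
      else if (score[i] == score[j]) num <- num + 0.5 * wij
    }
  }
  num / den
}

# Small discordant parameter set used by several behavioural tests.
demo_params <- function(n = 2000, seed = 11) {
  cohort_params(n_patients = n, p_lab_ordered = 1, seed = seed,
                p_visit_bmi_missing = 0.3, p_no_bmi_on_file = 0.4,
                p_structured_diabetes_history = 0.25,
                p_chart_only_diabetes_history = 0.10,
                p_structured_hba1c_within_3y = 0.15,
                p_chart_only_hba1c_within_3y = 0.08,
                p_exclusion_condition = 0.05)
}
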