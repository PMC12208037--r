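#' Chart-review reference standard
#'
#' Decides, from the full record, whether the advisory *should* have fired:
#' the same eligibility rule as [evaluate_bpa()], but evaluated on what a
#' chart reviewer can see — the chart-level diabetes-history and
#' HbA1c-lookback flags (which cover free text and external-network records)
#' and the BMI actually measured at the visit (`chart_bmi`, falling back to
#' the structured fields when absent). A visit with a condition that makes
#' HbA1c unreliable for diagnosis (pregnancy, sickle-cell anemia, HIV) should
#' never trigger: alerts on such visits count against the algorithm as false
#' positives, and silent visits count as true negatives.
#'
#' @param records data frame of patient-visit records including the chart
#'   view (`chart_diabetes_history`, `chart_hba1c_within_3y`,
#'   `exclusion_condition`, optionally `chart_bmi`).
#' @param config a [rule_config()]; the lab-order gate and the missing-BMI
#'   reading mirror the engine's configuration.
#' @return A data frame with one row per visit: `visit_id`, `should_trigger`
#'   (logical), `unreliable_hba1c` (logical), and `rationale_codes`
#'   (semicolon-joined codes among `truly_eligible`, `chart_diabetes_found`,
#'   `chart_hba1c_found`, `excluded_condition`, `age_bmi_ineligible`).
#' @examples
#' visit <- data.frame(visit_id = "V1", age = 50, visit_bmi = 28,
#'                     most_recent_bmi = NA_real_, chart_bmi = 28,
#'                     lab_ordered = TRUE,
#'                     structured_diabetes_history = FALSE,
#'                     chart_diabetes_history = TRUE,
#'                     structured_hba1c_within_3y = FALSE,
#'                     chart_hba1c_within_3y = FALSE,
#'                     exclusion_condition = "none")
#' review_chart(visit)  # chart-only diabetes history: should not trigger
#' @export
review_chart <- function(records, config = rule_config()) {
  check_records(records, need_chart = TRUE)
  n <- nrow(records)
  age <- records$age
  chart_bmi <- if ("chart_bmi" %in% names(records)) records$chart_bmi else rep(NA_real_, n)
  ref_bmi <- coalesce_num(chart_bmi, records$visit_bmi, records$most_recent_bmi)
  no_bmi <- is.na(ref_bmi)

  lab_ok <- if (config$require_lab_ordered) records$lab_ordered else rep(TRUE, n)
  age_known <- !is.na(age)
  age_alone <- age_known & age >= config$age_threshold_alone
  bmi_crit <- age_known & age >= config$age_threshold_with_bmi &
    !no_bmi & ref_bmi >= config$bmi_threshold
  demo <- (age_alone | bmi_crit)
  if (config$missing_bmi_suppresses_all) demo <- demo & !no_bmi

  cd <- records$chart_diabetes_history
  ch <- records$chart_hba1c_within_3y
  excluded <- records$exclusion_condition != "none"

  should <- lab_ok & age_known & demo & !cd & !ch & !excluded

  flags <- cbind(
    truly_eligible = should,
    chart_diabetes_found = cd,
    chart_hba1c_found = ch,
    excluded_condition = excluded,
    age_bmi_ineligible = !(age_known & demo)
  )

  data.frame(visit_id = records$visit_id,
             should_trigger = should,
             unreliable_hba1c = excluded,
             rationale_codes = join_codes(flags),
             stringsAsFactors = FALSE)
}

#' Classify decision/label pairs into confusion-matrix outcomes
#'
#' @param decisions data frame from [evaluate_bpa()] (needs `visit_id`,
#'   `triggered`).
#' @param labels data frame from [review_chart()] (needs `visit_id`,
#'   `should_trigger`).
#' @return A character vector (one element per decision row, in decision
#'   order) with values `"TP"`, `"FP"`, `"FN"`, `"TN"`.
#' @export
classify_pair <- function(decisions, labels) {
  if (!setequal(decisions$visit_id, labels$visit_id) ||
      nrow(decisions) != nrow(labels)) {
    stop("alignment error: decisions and labels must cover the same visit_ids",
         call. = FALSE)
  }
  lab <- labels$should_trigger[match(decisions$visit_id, labels$visit_id)]
  trig <- decisions$triggered
  ifelse(trig & lab, "TP",
         ifelse(trig & !lab, "FP",
                ifelse(!trig & lab, "FN", "TN")))
}
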