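#' Screening-rule configuration
#'
#' Thresholds and switches of the best-practice-advisory eligibility rule:
#' a visit qualifies when the patient is at least `age_threshold_alone` years
#' old, or at least `age_threshold_with_bmi` years old with a BMI of at least
#' `bmi_threshold` kg/m2; and has no recorded diabetes history and no HbA1c
#' result within `hba1c_lookback_years`. All comparisons are inclusive (>=).
#'
#' The lookback is consumed as a precomputed boolean on the record; when
#' preparing real data, compute it over a half-open window of
#' `hba1c_lookback_years * 365.25` days ending at the visit date.
#'
#' @param age_threshold_alone age (years) that qualifies regardless of BMI.
#' @param age_threshold_with_bmi minimum age (years) for the BMI criterion.
#' @param bmi_threshold BMI (kg/m2) for the age-plus-BMI criterion.
#' @param hba1c_lookback_years lookback window (years) for a prior HbA1c.
#' @param require_lab_ordered if `TRUE` (default) the advisory only fires on
#'   visits with an existing routine lab order it can ride on.
#' @param missing_bmi_suppresses_all if `TRUE`, a visit with no structured BMI
#'   anywhere never triggers, even via the age-alone criterion; the default
#'   `FALSE` lets the age-alone criterion fire without any BMI.
#' @return An object of class `rule_config`.
#' @export
rule_config <- function(age_threshold_alone = 45,
                        age_threshold_with_bmi = 18,
                        bmi_threshold = 25,
                        hba1c_lookback_years = 3,
                        require_lab_ordered = TRUE,
                        missing_bmi_suppresses_all = FALSE) {
  if (age_threshold_alone <= 0 || age_threshold_with_bmi <= 0 ||
      bmi_threshold <= 0 || hba1c_lookback_years <= 0) {
    stop("parameterization error: all rule thresholds must be positive", call. = FALSE)
  }
  if (age_threshold_with_bmi > age_threshold_alone) {
    stop("parameterization error: `age_threshold_with_bmi` must not exceed `age_threshold_alone`",
         call. = FALSE)
  }
  structure(list(age_threshold_alone = age_threshold_alone,
                 age_threshold_with_bmi = age_threshold_with_bmi,
                 bmi_threshold = bmi_threshold,
                 hba1c_lookback_years = hba1c_lookback_years,
                 require_lab_ordered = isTRUE(require_lab_ordered),
                 missing_bmi_suppresses_all = isTRUE(missing_bmi_suppresses_all)),
            class = "rule_config")
}

# Shared input validation for engine and reference standard.
check_records <- function(records, need_chart = FALSE) {
  required <- c("visit_id", "age", "visit_bmi", "most_recent_bmi", "lab_ordered",
                "structured_diabetes_history", "structured_hba1c_within_3y")
  if (need_chart) {
    required <- c(required, "chart_diabetes_history", "chart_hba1c_within_3y",
                  "exclusion_condition")
  }
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("validation error: records are missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- function(x) any(!is.na(x) & x < 0)
  if (bad(records$age) || bad(records$visit_bmi) || bad(records$most_recent_bmi) ||
      (need_chart && "chart_bmi" %in% names(records) && bad(records$chart_bmi))) {
    stop("validation error: negative age or BMI indicates corrupt input", call. = FALSE)
  }
  invisible(records)
}

#' Evaluate the screening advisory on the structured record
#'
#' The algorithm under validation. It sees only the structured
#' (algorithm-visible) view of each visit: `age`, `visit_bmi` with
#' `most_recent_bmi` as fallback, the structured diabetes-history flag, the
#' structured HbA1c-lookback flag, and the lab-order flag. Chart-only fields
#' never influence the verdict.
#'
#' The advisory fires iff (when required) a lab is ordered, age is present,
#' the age-alone criterion or the age-plus-effective-BMI criterion holds,
#' and both structured history flags are clear. Effective BMI is the visit
#' BMI when present, else the most recent BMI on file; when both are absent
#' the BMI criterion is unevaluable and — under the default reading — only
#' the age-alone criterion can fire.
#'
#' @param records data frame of patient-visit records (see
#'   [generate_cohort()] for the column contract); a single visit is a
#'   one-row data frame.
#' @param config a [rule_config()].
#' @return A data frame with one row per visit: `visit_id`, `triggered`
#'   (logical), and `reason_codes` (semicolon-joined machine-readable codes
#'   among `age_criterion_met`, `bmi_criterion_met`, `bmi_fallback_used`,
#'   `no_structured_diabetes`, `no_structured_hba1c`,
#'   `suppressed_missing_bmi`, `suppressed_missing_age`,
#'   `suppressed_no_lab`).
#' @examples
#' visit <- data.frame(visit_id = "V1", age = 50, visit_bmi = NA_real_,
#'                     most_recent_bmi = NA_real_, lab_ordered = TRUE,
#'                     structured_diabetes_history = FALSE,
#'                     structured_hba1c_within_3y = FALSE)
#' evaluate_bpa(visit)
#' @export
evaluate_bpa <- function(records, config = rule_config()) {
  check_records(records)
  n <- nrow(records)
  age <- records$age
  eff_bmi <- coalesce_num(records$visit_bmi, records$most_recent_bmi)
  fallback <- is.na(records$visit_bmi) & !is.na(records$most_recent_bmi)
  no_bmi <- is.na(eff_bmi)

  lab_ok <- if (config$require_lab_ordered) records$lab_ordered else rep(TRUE, n)
  age_known <- !is.na(age)
  age_alone <- age_known & age >= config$age_threshold_alone
  bmi_crit <- age_known & age >= config$age_threshold_with_bmi &
    !no_bmi & eff_bmi >= config$bmi_threshold

  demo <- (age_alone | bmi_crit)
  if (config$missing_bmi_suppresses_all) demo <- demo & !no_bmi

  sd_flag <- records$structured_diabetes_history
  sh_flag <- records$structured_hba1c_within_3y
  triggered <- lab_ok & age_known & demo & !sd_flag & !sh_flag

  # suppression due to missing BMI is flagged when the BMI criterion could
  # not be evaluated and the visit did not (or, strictly, may not) fire
  sup_bmi <- no_bmi & !triggered &
    (config$missing_bmi_suppresses_all | (age_known & age < config$age_threshold_alone))

  flags <- cbind(
    age_criterion_met = age_alone,
    bmi_criterion_met = bmi_crit,
    bmi_fallback_used = bmi_crit & fallback,
    no_structured_diabetes = !sd_flag,
    no_structured_hba1c = !sh_flag,
    suppressed_missing_bmi = sup_bmi,
    suppressed_missing_age = !age_known,
    suppressed_no_lab = !lab_ok
  )

  data.frame(visit_id = records$visit_id,
             triggered = triggered,
             reason_codes = join_codes(flags),
             stringsAsFactors = FALSE)
}
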