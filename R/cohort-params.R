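#' Parameters of the synthetic ED visit cohort
#'
#' Bundles every knob of the synthetic electronic-health-record cohort:
#' demographic marginals, eligibility-field distributions, missingness of the
#' structured BMI fields, discordance between the structured (algorithm-visible)
#' record and the full chart, HbA1c-unreliability conditions, and the
#' race/ethnicity strata used by the verification-sampling design.
#'
#' Defaults emulate a one-month urban academic ED census: mean age 48 (SD 17.9)
#' years truncated at 18, mean BMI 30.1 (SD 8.8) kg/m2, 77% of adult visits
#' with a routine lab ordered, and race/ethnicity stratum proportions taken as
#' exact count ratios of a 2,963-visit cohort so they sum to one.
#'
#' Discordance is modelled at the flag level: a chart-only history flag is a
#' condition documented in free text or an external-network record, visible to
#' chart review but not to the rule engine. Structured flags are always a
#' subset of chart flags (the chart search covers strictly more sources).
#'
#' @param n_patients number of ED visits to simulate (>= 1).
#' @param p_lab_ordered probability a visit has a routine lab ordered; only
#'   lab-ordered visits enter the validation cohort.
#' @param age_mean,age_sd,age_min truncated-normal age distribution (years);
#'   ages are reported as whole years, never below `age_min`.
#' @param bmi_mean,bmi_sd,bmi_min truncated-normal BMI distribution (kg/m2),
#'   recorded to one decimal.
#' @param p_visit_bmi_missing probability the structured visit-BMI field is
#'   blank (the measurement itself still exists in the chart).
#' @param p_no_bmi_on_file probability no historical BMI is on file, so the
#'   engine's fallback also fails; independent of `p_visit_bmi_missing`.
#' @param p_structured_diabetes_history probability of a structured
#'   (algorithm-visible) diabetes/prediabetes history.
#' @param p_chart_only_diabetes_history probability of an additional
#'   chart-only diabetes history (free text / external network).
#' @param p_structured_hba1c_within_3y probability of a structured HbA1c
#'   result within the three-year lookback.
#' @param p_chart_only_hba1c_within_3y probability of a chart-only HbA1c
#'   result within the lookback.
#' @param p_exclusion_condition probability of a condition that makes HbA1c
#'   unreliable (pregnancy, sickle-cell anemia, HIV).
#' @param exclusion_split named proportions splitting
#'   `p_exclusion_condition` across `pregnancy`, `sickle_cell`, `hiv`
#'   (must sum to 1).
#' @param strata_proportions named race/ethnicity proportions over
#'   `hispanic`, `white_nh`, `black_nh`, `asian_nh`, `other_nh`, `unknown`
#'   (must sum to 1 within 1e-9).
#' @param p_female probability a visit is female.
#' @param insurance_proportions named proportions over insurance categories.
#' @param seed integer seed; identical parameters (including seed) always
#'   reproduce the identical cohort.
#'
#' @return An object of class `cohort_params` (a validated named list).
#' @seealso [generate_cohort()], [calibrate_to_cells()], [expected_cells()]
#' @export
cohort_params <- function(n_patients = 2963,
                          p_lab_ordered = 2963 / 3850,
                          age_mean = 48, age_sd = 17.9, age_min = 18,
                          bmi_mean = 30.1, bmi_sd = 8.8, bmi_min = 12,
                          p_visit_bmi_missing = 0.10,
                          p_no_bmi_on_file = 0.30,
                          p_structured_diabetes_history = 0.20,
                          p_chart_only_diabetes_history = 0.05,
                          p_structured_hba1c_within_3y = 0.15,
                          p_chart_only_hba1c_within_3y = 0.05,
                          p_exclusion_condition = 0.02,
                          exclusion_split = c(pregnancy = 0.50,
                                              sickle_cell = 0.25,
                                              hiv = 0.25),
                          strata_proportions = c(hispanic = 763,
                                                 white_nh = 290,
                                                 black_nh = 1649,
                                                 asian_nh = 99,
                                                 other_nh = 125,
                                                 unknown = 37) / 2963,
                          p_female = 1781 / 2963,
                          insurance_proportions = c(medicaid = 1374,
                                                    medicare = 760,
                                                    private = 613,
                                                    other = 36,
                                                    uninsured = 180) / 2963,
                          seed = 1L) {
  params <- list(
    n_patients = n_patients,
    p_lab_ordered = p_lab_ordered,
    age_mean = age_mean, age_sd = age_sd, age_min = age_min,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd, bmi_min = bmi_min,
    p_visit_bmi_missing = p_visit_bmi_missing,
    p_no_bmi_on_file = p_no_bmi_on_file,
    p_structured_diabetes_history = p_structured_diabetes_history,
    p_chart_only_diabetes_history = p_chart_only_diabetes_history,
    p_structured_hba1c_within_3y = p_structured_hba1c_within_3y,
    p_chart_only_hba1c_within_3y = p_chart_only_hba1c_within_3y,
    p_exclusion_condition = p_exclusion_condition,
    exclusion_split = exclusion_split,
    strata_proportions = strata_proportions,
    p_female = p_female,
    insurance_proportions = insurance_proportions,
    seed = seed
  )
  class(params) <- "cohort_params"
  validate_cohort_params(params)
}

#' Validate cohort parameters
#'
#' @param params a `cohort_params` object or compatible list.
#' @return The validated `cohort_params` object, invisibly usable downstream.
#' @export
validate_cohort_params <- function(params) {
  if (!is.list(params)) stop("parameterization error: params must be a list", call. = FALSE)
  if (!is.numeric(params$n_patients) || length(params$n_patients) != 1L ||
      is.na(params$n_patients) || params$n_patients < 1 ||
      params$n_patients != floor(params$n_patients)) {
    stop("parameterization error: `n_patients` must be an integer >= 1", call. = FALSE)
  }
  for (p in c("p_lab_ordered", "p_visit_bmi_missing", "p_no_bmi_on_file",
              "p_structured_diabetes_history", "p_chart_only_diabetes_history",
              "p_structured_hba1c_within_3y", "p_chart_only_hba1c_within_3y",
              "p_exclusion_condition", "p_female")) {
    stop_if_not_prob(params[[p]], p)
  }
  if (params$age_sd <= 0 || params$bmi_sd <= 0) {
    stop("parameterization error: age and BMI standard deviations must be positive",
         call. = FALSE)
  }
  if (params$age_min < 18) {
    stop("parameterization error: the cohort is adults only; `age_min` must be >= 18",
         call. = FALSE)
  }
  if (params$bmi_min <= 0) {
    stop("parameterization error: `bmi_min` must be positive", call. = FALSE)
  }
  sp <- params$strata_proportions
  if (is.null(names(sp)) || length(sp) == 0L) {
    stop("parameterization error: `strata_proportions` must be a non-empty named vector",
         call. = FALSE)
  }
  if (any(sp < 0) || abs(sum(sp) - 1) > 1e-9) {
    stop("parameterization error: `strata_proportions` must be non-negative and sum to 1 (within 1e-9)",
         call. = FALSE)
  }
  es <- params$exclusion_split
  if (!setequal(names(es), c("pregnancy", "sickle_cell", "hiv")) ||
      any(es < 0) || abs(sum(es) - 1) > 1e-9) {
    stop("parameterization error: `exclusion_split` must name pregnancy/sickle_cell/hiv and sum to 1",
         call. = FALSE)
  }
  ip <- params$insurance_proportions
  if (is.null(names(ip)) || any(ip < 0) || abs(sum(ip) - 1) > 1e-9) {
    stop("parameterization error: `insurance_proportions` must be named, non-negative, sum to 1",
         call. = FALSE)
  }
  if (!is.null(params$seed) &&
      (!is.numeric(params$seed) || length(params$seed) != 1L || is.na(params$seed))) {
    stop("parameterization error: `seed` must be a single integer or NULL", call. = FALSE)
  }
  params
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("Synthetic ED cohort parameters\n")
  cat(sprintf("  visits: %d   P(lab ordered): %.3f   seed: %s\n",
              x$n_patients, x$p_lab_ordered,
              if (is.null(x$seed)) "none" else format(x$seed)))
  cat(sprintf("  age ~ TN(%.1f, %.1f; >=%g) y    BMI ~ TN(%.1f, %.1f; >=%g) kg/m2\n",
              x$age_mean, x$age_sd, x$age_min, x$bmi_mean, x$bmi_sd, x$bmi_min))
  cat(sprintf("  structured BMI missing: visit %.3f x no-file %.3f\n",
              x$p_visit_bmi_missing, x$p_no_bmi_on_file))
  cat(sprintf("  diabetes history: structured %.3f + chart-only %.3f\n",
              x$p_structured_diabetes_history, x$p_chart_only_diabetes_history))
  cat(sprintf("  HbA1c within 3y:  structured %.3f + chart-only %.3f\n",
              x$p_structured_hba1c_within_3y, x$p_chart_only_hba1c_within_3y))
  cat(sprintf("  HbA1c-unreliable condition: %.3f\n", x$p_exclusion_condition))
  cat("  strata: ", paste(sprintf("%s %.3f", names(x$strata_proportions),
                                  x$strata_proportions), collapse = ", "), "\n")
  invisible(x)
}
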