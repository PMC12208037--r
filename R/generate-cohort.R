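#' Generate a synthetic ED visit cohort
#'
#' Draws `n_patients` emergency-department visits with a structured
#' (algorithm-visible) view and a chart (reference-standard-visible) view of
#' the same history. One RNG stream seeded from `params$seed` feeds the fields
#' in a fixed documented order (stratum, sex, insurance, lab order, age, BMI,
#' visit-BMI missingness, BMI-on-file, structured then chart-only diabetes
#' history, structured then chart-only HbA1c history, exclusion condition), so
#' identical parameters reproduce identical cohorts on any platform.
#'
#' Chart flags are supersets of structured flags by construction: a chart flag
#' is the structured flag OR an independent chart-only documentation event.
#' `chart_bmi` carries the BMI actually measured at the visit — chart review
#' can always see it, while the engine only sees `visit_bmi` (blank with
#' probability `p_visit_bmi_missing`) and the historical fallback
#' `most_recent_bmi` (absent with probability `p_no_bmi_on_file`).
#'
#' @param params a [cohort_params()] object.
#' @return A data frame with one row per visit and columns `visit_id`, `age`,
#'   `visit_bmi`, `most_recent_bmi`, `chart_bmi`, `lab_ordered`,
#'   `structured_diabetes_history`, `chart_diabetes_history`,
#'   `structured_hba1c_within_3y`, `chart_hba1c_within_3y`,
#'   `exclusion_condition`, `race_ethnicity`, `sex`, `insurance`.
#'   Absent values are `NA`.
#' @examples
#' cohort <- generate_cohort(cohort_params(n_patients = 100, seed = 42))
#' table(cohort$race_ethnicity)
#' @export
generate_cohort <- function(params) {
  params <- validate_cohort_params(params)
  n <- params$n_patients
  if (!is.null(params$seed)) set.seed(as.integer(params$seed))

  race <- sample(names(params$strata_proportions), n, replace = TRUE,
                 prob = params$strata_proportions)
  sex <- ifelse(stats::runif(n) < params$p_female, "female", "male")
  insurance <- sample(names(params$insurance_proportions), n, replace = TRUE,
                      prob = params$insurance_proportions)
  lab_ordered <- stats::runif(n) < params$p_lab_ordered

  age <- as.integer(round_half_up(
    rtrunc_norm(n, params$age_mean, params$age_sd, params$age_min)))
  true_bmi <- round_half_up(
    rtrunc_norm(n, params$bmi_mean, params$bmi_sd, params$bmi_min), 1)

  visit_missing <- stats::runif(n) < params$p_visit_bmi_missing
  no_file <- stats::runif(n) < params$p_no_bmi_on_file

  sd_flag <- stats::runif(n) < params$p_structured_diabetes_history
  cd_extra <- stats::runif(n) < params$p_chart_only_diabetes_history
  sh_flag <- stats::runif(n) < params$p_structured_hba1c_within_3y
  ch_extra <- stats::runif(n) < params$p_chart_only_hba1c_within_3y

  p_ex <- params$p_exclusion_condition
  excl <- sample(c("none", names(params$exclusion_split)), n, replace = TRUE,
                 prob = c(1 - p_ex, p_ex * params$exclusion_split))

  data.frame(
    visit_id = sprintf("V%06d", seq_len(n)),
    age = age,
    visit_bmi = ifelse(visit_missing, NA_real_, true_bmi),
    most_recent_bmi = ifelse(no_file, NA_real_, true_bmi),
    chart_bmi = true_bmi,
    lab_ordered = lab_ordered,
    structured_diabetes_history = sd_flag,
    chart_diabetes_history = sd_flag | cd_extra,
    structured_hba1c_within_3y = sh_flag,
    chart_hba1c_within_3y = sh_flag | ch_extra,
    exclusion_condition = excl,
    race_ethnicity = race,
    sex = sex,
    insurance = insurance,
    stringsAsFactors = FALSE
  )
}

#' Expected confusion-cell probabilities under the generative model
#'
#' Closed-form map from cohort parameters to the expected TP/FP/FN/TN
#' proportions of the lab-ordered validation cohort, for the rule engine and
#' chart-review reference standard shipped in this package. Writing
#' \eqn{a = P(\mathrm{age} \ge 45)}, \eqn{b = P(\mathrm{BMI} \ge 25)},
#' \eqn{m} = probability both structured BMI fields are blank
#' (`p_visit_bmi_missing * p_no_bmi_on_file`), \eqn{s} = probability of a
#' clean structured history (no structured diabetes, no structured HbA1c),
#' \eqn{c} = probability of a clean chart beyond the structured record, and
#' \eqn{x = 1 - } `p_exclusion_condition`:
#' \deqn{P(\mathrm{eng}) = a + (1-a)\,b\,(1-m), \qquad
#'       P(\mathrm{fn\,base}) = (1-a)\,b\,m}
#' \deqn{TP = P(\mathrm{eng})\,s\,c\,x, \quad
#'       FP = P(\mathrm{eng})\,s\,(1-c\,x), \quad
#'       FN = P(\mathrm{fn\,base})\,s\,c\,x, \quad
#'       TN = 1 - TP - FP - FN.}
#' Under the strict missing-BMI reading (see [rule_config()]),
#' \eqn{P(\mathrm{eng}) = (1-m)(a + (1-a)b)} and
#' \eqn{P(\mathrm{fn\,base}) = m\,(a + (1-a)b)}.
#'
#' `a` and `b` use the same recording conventions as the generator (ages are
#' whole years, BMI has one decimal), so thresholds act at 44.5 years and
#' 24.95 kg/m2 on the underlying continuous scales.
#'
#' @param params a [cohort_params()] object.
#' @param config a [rule_config()]; thresholds and missing-BMI reading.
#' @return Named numeric vector `c(tp, fp, fn, tn)` of probabilities summing
#'   to 1, with the intermediate quantities `a`, `b`, `m`, `s`, `c`, `x`
#'   attached as attribute `"components"`.
#' @export
expected_cells <- function(params, config = rule_config()) {
  params <- validate_cohort_params(params)
  a <- ptrunc_norm_upper(config$age_threshold_alone - 0.5,
                         params$age_mean, params$age_sd, params$age_min)
  b <- ptrunc_norm_upper(config$bmi_threshold - 0.05,
                         params$bmi_mean, params$bmi_sd, params$bmi_min)
  m <- params$p_visit_bmi_missing * params$p_no_bmi_on_file
  s <- (1 - params$p_structured_diabetes_history) *
       (1 - params$p_structured_hba1c_within_3y)
  cc <- (1 - params$p_chart_only_diabetes_history) *
        (1 - params$p_chart_only_hba1c_within_3y)
  x <- 1 - params$p_exclusion_condition

  if (isTRUE(config$missing_bmi_suppresses_all)) {
    p_eng <- (1 - m) * (a + (1 - a) * b)
    p_fn_base <- m * (a + (1 - a) * b)
  } else {
    p_eng <- a + (1 - a) * b * (1 - m)
    p_fn_base <- (1 - a) * b * m
  }

  tp <- p_eng * s * cc * x
  fp <- p_eng * s * (1 - cc * x)
  fn <- p_fn_base * s * cc * x
  cells <- c(tp = tp, fp = fp, fn = fn, tn = 1 - tp - fp - fn)
  attr(cells, "components") <- c(a = a, b = b, m = m, s = s, c = cc, x = x)
  cells
}

#' Calibrate generator parameters to target confusion-table cells
#'
#' Inverts the closed-form map of [expected_cells()]: given target TP/FP/FN/TN
#' counts (or proportions), solves for the missing-BMI, structured-history and
#' chart-only discordance probabilities so that the expected 2x2 of a cohort
#' generated under the returned parameters matches the target proportions.
#'
#' With target shares \eqn{t_{TP}, t_{FP}, t_{FN}} (of the lab-ordered
#' cohort), \eqn{a} and \eqn{b} fixed by the demographic distributions of
#' `base`, and \eqn{x} fixed by `base`'s exclusion probability:
#' \deqn{c\,x = t_{TP}/(t_{TP}+t_{FP}), \qquad r = t_{FN}/t_{TP},}
#' \deqn{m = \frac{r\,(a + (1-a)b)}{(1+r)\,(1-a)\,b}, \qquad
#'       s = \frac{t_{TP}+t_{FP}}{a + (1-a)b(1-m)}.}
#' The joint probabilities \eqn{m}, \eqn{s} and \eqn{c} are split evenly
#' across their two constituent channels (square-root split); any split with
#' the same product gives identical expected cells.
#'
#' @param target a [confusion_table()] or numeric vector
#'   `c(tp, fp, fn, tn)` of non-negative cells with positive total.
#' @param base a [cohort_params()] object supplying everything the target
#'   does not identify (demographics, strata, exclusion probability, seed).
#' @param config a [rule_config()] (the default missing-BMI reading is
#'   assumed by the inversion).
#' @return A `cohort_params` object whose [expected_cells()] equal the target
#'   proportions (up to numerical precision). Solved components are attached
#'   as attribute `"calibration"`.
#' @examples
#' params <- calibrate_to_cells(c(tp = 599, fp = 197, fn = 265, tn = 1902))
#' round(expected_cells(params), 4)
#' @export
calibrate_to_cells <- function(target, base = cohort_params(),
                               config = rule_config()) {
  tgt <- as_cells(target)
  if (any(tgt < 0) || sum(tgt) <= 0) {
    stop("calibration error: target cells must be non-negative with positive total",
         call. = FALSE)
  }
  if (isTRUE(config$missing_bmi_suppresses_all)) {
    stop("calibration error: closed-form inversion assumes the default missing-BMI reading",
         call. = FALSE)
  }
  base <- validate_cohort_params(base)
  shares <- tgt / sum(tgt)
  t_tp <- shares[["tp"]]; t_fp <- shares[["fp"]]; t_fn <- shares[["fn"]]

  comp <- attr(expected_cells(base, config), "components")
  a <- comp[["a"]]; b <- comp[["b"]]
  x <- 1 - base$p_exclusion_condition

  if (t_tp == 0) {
    if (t_fp > 0 || t_fn > 0) {
      stop("calibration error: infeasible target — FP or FN demanded with zero TP",
           call. = FALSE)
    }
    # all-negative target: silence the engine entirely
    m <- 0; s <- 0; cx <- x
  } else {
    cx <- t_tp / (t_tp + t_fp)
    r <- t_fn / t_tp
    m <- r * (a + (1 - a) * b) / ((1 + r) * (1 - a) * b)
    if (m > 1 + 1e-12) {
      stop(sprintf(paste0("calibration error: infeasible target — FN/TP ratio %.3f exceeds ",
                          "the capacity of the missing-BMI channel (max %.3f under the ",
                          "base demographics)"), r, (1 - a) * b / a), call. = FALSE)
    }
    m <- min(max(m, 0), 1)
    p_eng <- a + (1 - a) * b * (1 - m)
    s <- (t_tp + t_fp) / p_eng
    if (s > 1 + 1e-12) {
      stop("calibration error: infeasible target — demanded alert rate exceeds demographic eligibility",
           call. = FALSE)
    }
    s <- min(s, 1)
  }
  if (cx > x + 1e-12) {
    stop(sprintf(paste0("calibration error: infeasible target — base exclusion probability %.3f ",
                        "already exceeds the demanded false-positive share among alerts"),
                 base$p_exclusion_condition), call. = FALSE)
  }
  cc <- min(cx / x, 1)

  out <- base
  out$p_visit_bmi_missing <- sqrt(m)
  out$p_no_bmi_on_file <- sqrt(m)
  out$p_structured_diabetes_history <- 1 - sqrt(s)
  out$p_structured_hba1c_within_3y <- 1 - sqrt(s)
  out$p_chart_only_diabetes_history <- 1 - sqrt(cc)
  out$p_chart_only_hba1c_within_3y <- 1 - sqrt(cc)
  out <- validate_cohort_params(out)
  attr(out, "calibration") <- c(a = a, b = b, m = m, s = s, c = cc, x = x)
  out
}

# Accept a confusion_table or a (possibly named) length-4 numeric vector.
as_cells <- function(target) {
  if (inherits(target, "confusion_table")) {
    return(c(tp = target$tp, fp = target$fp, fn = target$fn, tn = target$tn))
  }
  if (is.numeric(target) && length(target) == 4L) {
    if (!is.null(names(target)) && setequal(names(target), c("tp", "fp", "fn", "tn"))) {
      return(target[c("tp", "fp", "fn", "tn")])
    }
    return(stats::setNames(as.numeric(target), c("tp", "fp", "fn", "tn")))
  }
  stop("calibration error: target must be a confusion_table or length-4 numeric (tp, fp, fn, tn)",
       call. = FALSE)
}
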