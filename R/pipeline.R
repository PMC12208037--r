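#' Pipeline configuration
#'
#' Bundles the three parameter objects and the run options of the
#' end-to-end validation pipeline.
#'
#' @param cohort a [cohort_params()] object.
#' @param rules a [rule_config()] object.
#' @param design a [sampling_design()] object.
#' @param mode `"census"` (every visit's reference label enters the 2x2
#'   with weight 1; the synthetic default) or `"verification"` (only
#'   alert-positives and the stratified negative sample are verified, with
#'   Horvitz-Thompson weights extrapolating to the cohort).
#' @param n_boot_auc bootstrap replicates for the AUC interval.
#' @param auc_seed seed for the AUC bootstrap.
#' @param report_precision decimal places used when printing reports.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_params(),
                            rules = rule_config(),
                            design = sampling_design(seed = 1L),
                            mode = c("census", "verification"),
                            n_boot_auc = 2000,
                            auc_seed = 1L,
                            report_precision = 2) {
  mode <- match.arg(mode)
  cohort <- validate_cohort_params(cohort)
  stopifnot(inherits(rules, "rule_config"), inherits(design, "sampling_design"))
  if (!is.numeric(n_boot_auc) || n_boot_auc < 0) {
    stop("parameterization error: `n_boot_auc` must be a non-negative count", call. = FALSE)
  }
  structure(list(cohort = cohort, rules = rules, design = design, mode = mode,
                 n_boot_auc = n_boot_auc, auc_seed = auc_seed,
                 report_precision = report_precision),
            class = "pipeline_config")
}

#' Run the full validation pipeline
#'
#' Generate the synthetic ED cohort, keep the lab-ordered visits, run the
#' rule engine and the chart-review reference standard, draw the
#' verification sample (in `"verification"` mode), build the (weighted)
#' confusion table, and compute the accuracy report, likelihood ratios,
#' weighted AUC and acceptability verdicts. With `output_dir` set, the
#' stage artifacts are written as plain-text files (`cohort.csv`,
#' `decisions.csv`, `labels.csv`, `confusion.json`, `report.json`,
#' `cascade.json`, `roc.csv`). Fixed seeds make the whole run — including
#' `report.json` — byte-reproducible.
#'
#' @param config a [pipeline_config()] object.
#' @param output_dir directory for artifacts, or `NULL` to skip writing.
#' @return A list with `cohort`, `analysis_cohort` (lab-ordered subset),
#'   `decisions`, `labels`, `verification` (weights frame or `NULL`),
#'   `confusion`, `report` (an [accuracy_report()] including the AUC),
#'   `verdicts`, `auc` (full [weighted_auc()] result), and `cascade`
#'   (visit counts down the funnel: adults, lab ordered, alert triggered).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- generate_cohort(config$cohort)
  analysis <- cohort[cohort$lab_ordered, , drop = FALSE]
  if (nrow(analysis) == 0L) {
    stop("pipeline error [stage: cohort]: no lab-ordered visits to validate", call. = FALSE)
  }

  decisions <- tryCatch(evaluate_bpa(analysis, config$rules),
                        error = function(e) stop("pipeline error [stage: engine]: ",
                                                 conditionMessage(e), call. = FALSE))
  labels <- tryCatch(review_chart(analysis, config$rules),
                     error = function(e) stop("pipeline error [stage: review]: ",
                                              conditionMessage(e), call. = FALSE))

  verification <- NULL
  weights <- NULL
  if (config$mode == "verification") {
    verification <- sample_negatives(analysis, decisions, config$design)
    weights <- verification[, c("visit_id", "weight")]
  }

  confusion <- build_confusion(decisions, labels, weights)
  auc <- weighted_auc(analysis, decisions, labels, weights,
                      n_boot = config$n_boot_auc, seed = config$auc_seed)
  report <- accuracy_report(confusion, auc = auc$metric)
  verdicts <- acceptability(report)

  cascade <- c(adults = nrow(cohort),
               lab_ordered = nrow(analysis),
               bpa_triggered = sum(decisions$triggered))

  result <- list(cohort = cohort, analysis_cohort = analysis,
                 decisions = decisions, labels = labels,
                 verification = verification, confusion = confusion,
                 report = report, verdicts = verdicts, auc = auc,
                 cascade = cascade)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(output_dir, f)
    write_cohort_csv(cohort, p("cohort.csv"))
    utils::write.csv(decisions, p("decisions.csv"), row.names = FALSE, na = "")
    utils::write.csv(labels, p("labels.csv"), row.names = FALSE, na = "")
    jsonlite::write_json(unclass(confusion), p("confusion.json"),
                         auto_unbox = TRUE, digits = 10)
    jsonlite::write_json(list(metrics = report$metrics, verdicts = verdicts),
                         p("report.json"), auto_unbox = TRUE, digits = 10)
    jsonlite::write_json(as.list(cascade), p("cascade.json"),
                         auto_unbox = TRUE, digits = 10)
    utils::write.csv(auc$roc, p("roc.csv"), row.names = FALSE)
  }
  result
}
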