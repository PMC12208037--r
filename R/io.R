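# Readers and writers for the pipeline's tabular artifacts.
# CSV dialect: RFC-4180, UTF-8, mandatory header, empty cell = absent value.

cohort_numeric_cols <- c("age", "visit_bmi", "most_recent_bmi", "chart_bmi")
cohort_logical_cols <- c("lab_ordered", "structured_diabetes_history",
                         "chart_diabetes_history", "structured_hba1c_within_3y",
                         "chart_hba1c_within_3y")

#' Write / read a cohort as CSV
#'
#' One row per visit, columns named exactly as the record fields; absent
#' values are written as empty cells and read back as `NA`, so a write/read
#' round trip reproduces the cohort exactly.
#'
#' @param cohort cohort data frame from [generate_cohort()].
#' @param path file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the cohort data frame with the documented column types.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (col in intersect(cohort_numeric_cols, names(df))) df[[col]] <- as.numeric(df[[col]])
  if ("age" %in% names(df)) df$age <- as.integer(df$age)
  for (col in intersect(cohort_logical_cols, names(df))) df[[col]] <- as.logical(df[[col]])
  df
}

#' Write / read a cohort as JSON lines
#'
#' One JSON object per line; absent values are `null`.
#'
#' @inheritParams write_cohort_csv
#' @return `write_cohort_jsonl` returns `path` invisibly; `read_cohort_jsonl`
#'   returns the cohort data frame.
#' @export
write_cohort_jsonl <- function(cohort, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(cohort))) {
    writeLines(jsonlite::toJSON(as.list(cohort[i, , drop = FALSE]),
                                auto_unbox = TRUE, na = "null", digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_cohort_jsonl
#' @export
read_cohort_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    x[vapply(x, is.null, logical(1))] <- NA
    as.data.frame(x, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  for (col in intersect(cohort_numeric_cols, names(df))) df[[col]] <- as.numeric(df[[col]])
  if ("age" %in% names(df)) df$age <- as.integer(df$age)
  df
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the three parameter objects: a `cohort` block with
#' [cohort_params()] fields (`exclusion_split`, `strata_proportions` and
#' `insurance_proportions` as named maps), a `rules` block with
#' [rule_config()] fields, and a `design` block with [sampling_design()]
#' fields. Missing blocks or fields fall back to the documented defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()] object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(fn, block) {
    args <- y[[block]]
    if (is.null(args)) return(fn())
    for (nm in c("exclusion_split", "strata_proportions", "insurance_proportions")) {
      if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
    }
    do.call(fn, args)
  }
  extra <- y[setdiff(names(y), c("cohort", "rules", "design"))]
  do.call(pipeline_config,
          c(list(cohort = build(cohort_params, "cohort"),
                 rules = build(rule_config, "rules"),
                 design = build(sampling_design, "design")),
            extra))
}
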