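#' Verification-sampling design
#'
#' Chart review is expensive, so only a stratified fraction of the
#' alert-negative visits is verified against the reference standard; every
#' alert-positive visit is always fully verified. Sampling is stratified by
#' race/ethnicity and each sampled negative carries a Horvitz-Thompson weight
#' (stratum population size divided by stratum sample size), so weighted cell
#' sums estimate the full-cohort 2x2 without bias.
#'
#' @param sampled_fraction fraction of negatives verified per stratum, in
#'   (0, 1]; 1 means a census (all weights 1).
#' @param seed integer seed for the within-stratum draws (or `NULL`).
#' @return An object of class `sampling_design`.
#' @export
sampling_design <- function(sampled_fraction = 0.10, seed = NULL) {
  if (!is.numeric(sampled_fraction) || length(sampled_fraction) != 1L ||
      is.na(sampled_fraction) || sampled_fraction <= 0 || sampled_fraction > 1) {
    stop("design error: `sampled_fraction` must be in (0, 1]", call. = FALSE)
  }
  structure(list(sampled_fraction = sampled_fraction, seed = seed),
            class = "sampling_design")
}

#' Draw the stratified verification sample of alert-negative visits
#'
#' Within each race/ethnicity stratum of the untriggered visits, draws
#' `round(fraction * n_stratum)` records without replacement (half-up
#' rounding) and assigns each the weight `n_stratum / n_sampled`. Triggered
#' visits are returned in full with weight 1. The weights of a stratum's
#' sample sum exactly to that stratum's negative population size.
#'
#' @param records cohort data frame (needs `visit_id`, `race_ethnicity`).
#' @param decisions data frame from [evaluate_bpa()] aligned with `records`.
#' @param design a [sampling_design()].
#' @return A data frame of the verified visits: `visit_id`, `race_ethnicity`,
#'   `triggered`, `weight`. Attribute `"stratum_table"` records, per stratum,
#'   the negative population and sample sizes.
#' @export
sample_negatives <- function(records, decisions, design = sampling_design()) {
  if (!setequal(records$visit_id, decisions$visit_id)) {
    stop("alignment error: records and decisions must cover the same visit_ids",
         call. = FALSE)
  }
  if (!"race_ethnicity" %in% names(records)) {
    stop("design error: every record must carry a race/ethnicity stratum", call. = FALSE)
  }
  trig <- decisions$triggered[match(records$visit_id, decisions$visit_id)]
  frac <- design$sampled_fraction
  if (!is.null(design$seed)) set.seed(as.integer(design$seed))

  pos <- data.frame(visit_id = records$visit_id[trig],
                    race_ethnicity = records$race_ethnicity[trig],
                    triggered = rep(TRUE, sum(trig)),
                    weight = rep(1, sum(trig)),
                    stringsAsFactors = FALSE)

  neg <- records[!trig, c("visit_id", "race_ethnicity")]
  strata <- sort(unique(neg$race_ethnicity))
  pieces <- vector("list", length(strata))
  tab <- data.frame(stratum = strata, n_negative = NA_integer_,
                    n_sampled = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(strata)) {
    ids <- neg$visit_id[neg$race_ethnicity == strata[i]]
    n_s <- length(ids)
    k <- as.integer(round_half_up(frac * n_s))
    if (n_s > 0 && k == 0) {
      stop(sprintf("design error: stratum '%s' has %d negatives but a sample of zero; increase `sampled_fraction`",
                   strata[i], n_s), call. = FALSE)
    }
    take <- if (k == n_s) ids else sample(ids, k)
    pieces[[i]] <- data.frame(visit_id = take, race_ethnicity = strata[i],
                              triggered = FALSE, weight = n_s / k,
                              stringsAsFactors = FALSE)
    tab$n_negative[i] <- n_s
    tab$n_sampled[i] <- k
  }
  out <- rbind(pos, do.call(rbind, pieces))
  rownames(out) <- NULL
  attr(out, "stratum_table") <- tab
  out
}
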