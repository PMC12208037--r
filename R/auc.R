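#' Weighted concordance (AUC) of a score against a binary outcome
#'
#' The weighted probability that a randomly chosen positive outranks a
#' randomly chosen negative, ties counted one half:
#' \deqn{AUC = \frac{\sum_{i \in pos} \sum_{j \in neg} w_i w_j
#'   \left( [s_i > s_j] + \tfrac12 [s_i = s_j] \right)}
#'   {\left(\sum_{i \in pos} w_i\right) \left(\sum_{j \in neg} w_j\right)}.}
#' Computed in O(n log n) by a single pass over the scores in sorted order,
#' accumulating the negative weight below each tie group.
#'
#' @param score numeric model scores.
#' @param positive logical outcome per score.
#' @param weight positive weights (default all 1).
#' @return The weighted AUC in `[0, 1]`.
#' @export
weighted_concordance <- function(score, positive, weight = rep(1, length(score))) {
  stopifnot(length(score) == length(positive), length(score) == length(weight))
  if (any(weight <= 0) || any(!is.finite(score))) {
    stop("validation error: weights must be positive and scores finite", call. = FALSE)
  }
  w_pos_tot <- sum(weight[positive])
  w_neg_tot <- sum(weight[!positive])
  if (w_pos_tot <= 0 || w_neg_tot <= 0) {
    stop("undefined-metric error: concordance needs both outcome classes", call. = FALSE)
  }
  o <- order(score)
  s <- score[o]; p <- positive[o]; w <- weight[o]
  grp <- cumsum(c(TRUE, s[-1] != s[-length(s)]))
  w_pos_g <- tapply(w * p, grp, sum)
  w_neg_g <- tapply(w * !p, grp, sum)
  below_neg <- cumsum(c(0, w_neg_g[-length(w_neg_g)]))
  num <- sum(w_pos_g * below_neg + 0.5 * w_pos_g * w_neg_g)
  as.numeric(num / (w_pos_tot * w_neg_tot))
}

#' Weighted logistic ROC/AUC for correct alert adjudication
#'
#' Fits a weight-adjusted logistic regression of the binary outcome "the
#' alert decision agreed with the chart-review reference" on the four rule
#' inputs — age (years, continuous), BMI (kg/m2, continuous, the
#' chart-verified value), chart diabetes history and chart HbA1c history —
#' and summarises the fitted scores by their weighted concordance
#' (the AUC). The confidence interval comes from a seeded bootstrap
#' stratified on the outcome (resampling records within the
#' correct/incorrect groups and refitting the model each time).
#'
#' Complete separation does not abort the computation: the fit is flagged
#' (`separation = TRUE`) and the AUC is still computed from the scores.
#'
#' @param records cohort data frame (needs `age`, a BMI view, and the chart
#'   history flags).
#' @param decisions data frame from [evaluate_bpa()].
#' @param labels data frame from [review_chart()].
#' @param weights `NULL` (census: unit weights for all records) or a data
#'   frame with `visit_id` and `weight` restricting the fit to the verified
#'   visits.
#' @param ci_level confidence level for the bootstrap percentile interval.
#' @param n_boot bootstrap replicates (default 2000; 0 skips the interval).
#' @param seed integer seed for the bootstrap.
#' @return A list with `metric` (AUC with `se` and percentile `ci_low` /
#'   `ci_high`), `model` (the fitted `glm`), `roc` (data frame of weighted
#'   FPR/TPR at every score threshold) and `separation`.
#' @export
weighted_auc <- function(records, decisions, labels, weights = NULL,
                         ci_level = 0.95, n_boot = 2000, seed = NULL) {
  if (is.null(weights)) {
    weights <- data.frame(visit_id = records$visit_id, weight = 1,
                          stringsAsFactors = FALSE)
  }
  rec <- records[match(weights$visit_id, records$visit_id), , drop = FALSE]
  dec <- decisions[match(weights$visit_id, decisions$visit_id), , drop = FALSE]
  lab <- labels[match(weights$visit_id, labels$visit_id), , drop = FALSE]
  if (any(is.na(dec$triggered)) || any(is.na(lab$should_trigger))) {
    stop("alignment error: weighted visit_ids must appear in records, decisions and labels",
         call. = FALSE)
  }
  chart_bmi <- if ("chart_bmi" %in% names(rec)) rec$chart_bmi else rep(NA_real_, nrow(rec))
  dat <- data.frame(
    correct = dec$triggered == lab$should_trigger,
    age = rec$age,
    bmi = coalesce_num(chart_bmi, rec$visit_bmi, rec$most_recent_bmi),
    diabetes_history = rec$chart_diabetes_history,
    hba1c_history = rec$chart_hba1c_within_3y,
    w = weights$weight
  )
  dat$bmi[is.na(dat$bmi)] <- stats::median(dat$bmi, na.rm = TRUE)
  if (length(unique(dat$correct)) < 2L) {
    stop("undefined-metric error: both outcome classes (correct / incorrect adjudication) are required",
         call. = FALSE)
  }

  fit_auc <- function(d) {
    fit <- suppressWarnings(stats::glm(
      correct ~ age + bmi + diabetes_history + hba1c_history,
      family = stats::quasibinomial(), data = d, weights = d$w))
    score <- stats::predict(fit, type = "link")
    list(fit = fit,
         auc = weighted_concordance(score, d$correct, d$w),
         score = score)
  }

  full <- fit_auc(dat)
  separation <- !full$fit$converged || any(abs(stats::coef(full$fit)) > 15, na.rm = TRUE)
  if (separation) {
    warning("possible complete separation in the weighted logistic model; AUC computed from the fitted scores anyway")
  }

  est <- full$auc
  se <- NA_real_; lo <- NA_real_; hi <- NA_real_
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    idx_pos <- which(dat$correct)
    idx_neg <- which(!dat$correct)
    boots <- vapply(seq_len(n_boot), function(b) {
      ii <- c(sample(idx_pos, length(idx_pos), replace = TRUE),
              sample(idx_neg, length(idx_neg), replace = TRUE))
      fit_auc(dat[ii, , drop = FALSE])$auc
    }, numeric(1))
    se <- stats::sd(boots)
    alpha <- 1 - ci_level
    qs <- stats::quantile(boots, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
    lo <- qs[1]; hi <- qs[2]
  }

  # weighted ROC points over all score thresholds
  ord <- order(full$score, decreasing = TRUE)
  s <- full$score[ord]; y <- dat$correct[ord]; w <- dat$w[ord]
  tpr <- cumsum(w * y) / sum(w * y)
  fpr <- cumsum(w * !y) / sum(w * !y)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  roc <- data.frame(threshold = s[keep], fpr = fpr[keep], tpr = tpr[keep])
  roc <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), roc)

  list(metric = list(name = "auc", estimate = est, se = se,
                     ci_low = lo, ci_high = hi, ci_level = ci_level),
       model = full$fit, roc = roc, separation = separation)
}
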