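#' Confusion table of alert decisions against the reference standard
#'
#' @param tp,fp,fn,tn non-negative (possibly weighted) cell counts: alerts
#'   that should have fired (TP), alerts that should not have (FP), silent
#'   visits that should have alerted (FN), correctly silent visits (TN).
#' @return An object of class `confusion_table`.
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop("validation error: confusion cells must be finite and non-negative", call. = FALSE)
  }
  if (sum(cells) <= 0) {
    stop("validation error: confusion table total must be positive", call. = FALSE)
  }
  structure(as.list(cells), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, digits = 1, ...) {
  m <- matrix(c(x$tp, x$fp, x$tp + x$fp,
                x$fn, x$tn, x$fn + x$tn,
                x$tp + x$fn, x$fp + x$tn, x$tp + x$fp + x$fn + x$tn),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("alert fired", "no alert", "total"),
                              c("should fire", "should not", "total")))
  print(round(m, digits))
  invisible(x)
}

#' Build the (optionally weighted) confusion table
#'
#' Each cell is the sum of verification weights of the decision/label pairs
#' classified into it by [classify_pair()]. With unit weights (the census
#' mode) cells are plain integer counts; with a verification sample the
#' weighted cells extrapolate the verified subsample to the full cohort.
#'
#' @param decisions data frame from [evaluate_bpa()].
#' @param labels data frame from [review_chart()]; in verification-sample
#'   mode only the verified visits need labels.
#' @param weights `NULL` for unit weights, or a data frame with `visit_id`
#'   and `weight` (e.g. from [sample_negatives()]); only weighted visits
#'   enter the table.
#' @return A [confusion_table()].
#' @export
build_confusion <- function(decisions, labels, weights = NULL) {
  if (is.null(weights)) {
    weights <- data.frame(visit_id = decisions$visit_id, weight = 1,
                          stringsAsFactors = FALSE)
  }
  if (any(weights$weight <= 0)) {
    stop("validation error: verification weights must be positive", call. = FALSE)
  }
  if (!all(weights$visit_id %in% decisions$visit_id) ||
      !all(weights$visit_id %in% labels$visit_id)) {
    stop("alignment error: weighted visit_ids must appear in both decisions and labels",
         call. = FALSE)
  }
  dec <- decisions[match(weights$visit_id, decisions$visit_id), , drop = FALSE]
  lab <- labels[match(weights$visit_id, labels$visit_id), , drop = FALSE]
  cls <- classify_pair(dec, lab)
  cell <- function(k) sum(weights$weight[cls == k])
  confusion_table(tp = cell("TP"), fp = cell("FP"),
                  fn = cell("FN"), tn = cell("TN"))
}

# One diagnostic metric with Wald machinery.
make_metric <- function(name, estimate, se, ci_level, bounded01 = TRUE) {
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  lo <- estimate - z * se
  hi <- estimate + z * se
  if (bounded01) {
    lo <- max(0, lo)
    hi <- min(1, hi)
  } else {
    lo <- max(0, lo)
  }
  list(name = name, estimate = estimate, se = se,
       ci_low = lo, ci_high = hi, ci_level = ci_level)
}

#' Sensitivity, specificity and predictive values with Wald intervals
#'
#' Proportion estimates from the (possibly weighted) 2x2:
#' sens = TP/(TP+FN), spec = TN/(TN+FP), PPV = TP/(TP+FP), NPV = TN/(TN+FN);
#' each with the binomial standard error `sqrt(p (1-p) / n)` over its own
#' denominator and a natural-scale Wald interval truncated to `[0, 1]`.
#'
#' @param ct a [confusion_table()].
#' @param ci_level confidence level (default 0.95).
#' @return An object of class `accuracy_report` holding the four metrics
#'   (each with `estimate`, `se`, `ci_low`, `ci_high`) and the input table.
#' @examples
#' accuracy_metrics(confusion_table(599, 197, 265, 1902))
#' @export
accuracy_metrics <- function(ct, ci_level = 0.95) {
  stopifnot(inherits(ct, "confusion_table"))
  stop_if_not_prob(ci_level, "ci_level")
  defs <- list(sensitivity = c("tp", "fn"),
               specificity = c("tn", "fp"),
               ppv = c("tp", "fp"),
               npv = c("tn", "fn"))
  metrics <- list()
  for (nm in names(defs)) {
    num <- ct[[defs[[nm]][1]]]
    den <- num + ct[[defs[[nm]][2]]]
    if (den <= 0) {
      stop(sprintf("undefined-metric error: %s has a zero denominator", nm),
           call. = FALSE)
    }
    p <- num / den
    se <- sqrt(p * (1 - p) / den)
    metrics[[nm]] <- make_metric(nm, p, se, ci_level)
  }
  structure(list(metrics = metrics, table = ct, ci_level = ci_level),
            class = "accuracy_report")
}

#' Likelihood ratios with delta-method intervals
#'
#' LR+ = sens/(1-spec) and LR- = (1-sens)/spec, with standard errors by the
#' delta method on the log scale back-transformed to the natural scale:
#' \deqn{Var(\ln LR^+) = \frac{1-sens}{sens \cdot n_{pos}} +
#'       \frac{spec}{(1-spec)\, n_{neg}}, \qquad
#'       Var(\ln LR^-) = \frac{sens}{(1-sens)\, n_{pos}} +
#'       \frac{1-spec}{spec \cdot n_{neg}},}
#' with \eqn{n_{pos} = TP+FN}, \eqn{n_{neg} = FP+TN},
#' \eqn{SE(LR) = LR \cdot \sqrt{Var(\ln LR)}}, and a natural-scale Wald
#' interval (the default, which matches reports that print an SE next to a
#' symmetric CI) or a log-scale interval `exp(ln LR +/- z sqrt(Var))`.
#'
#' A perfect specificity makes LR+ infinite and a zero specificity makes LR-
#' infinite; these return `Inf` estimates with `NA` uncertainty rather than
#' failing.
#'
#' @param ct a [confusion_table()].
#' @param ci_level confidence level (default 0.95).
#' @param ci_scale `"natural"` (default) or `"log"`.
#' @return A list with elements `lr_pos` and `lr_neg`, each a metric list
#'   (`estimate`, `se`, `ci_low`, `ci_high`).
#' @examples
#' likelihood_ratios(confusion_table(599, 197, 265, 1902))
#' @export
likelihood_ratios <- function(ct, ci_level = 0.95,
                              ci_scale = c("natural", "log")) {
  stopifnot(inherits(ct, "confusion_table"))
  ci_scale <- match.arg(ci_scale)
  n_pos <- ct$tp + ct$fn
  n_neg <- ct$fp + ct$tn
  if (n_pos <= 0 || n_neg <= 0) {
    stop("undefined-metric error: likelihood ratios need both reference classes",
         call. = FALSE)
  }
  sens <- ct$tp / n_pos
  spec <- ct$tn / n_neg
  z <- stats::qnorm(1 - (1 - ci_level) / 2)

  one_lr <- function(est, var_log, name) {
    if (!is.finite(est)) {
      return(list(name = name, estimate = Inf, se = NA_real_,
                  ci_low = NA_real_, ci_high = NA_real_, ci_level = ci_level))
    }
    se <- est * sqrt(var_log)
    if (ci_scale == "natural") {
      list(name = name, estimate = est, se = se,
           ci_low = max(0, est - z * se), ci_high = est + z * se,
           ci_level = ci_level)
    } else {
      list(name = name, estimate = est, se = se,
           ci_low = est * exp(-z * sqrt(var_log)),
           ci_high = est * exp(z * sqrt(var_log)),
           ci_level = ci_level)
    }
  }

  lr_pos <- if (spec >= 1) Inf else sens / (1 - spec)
  lr_neg <- if (spec <= 0) Inf else (1 - sens) / spec
  var_log_pos <- if (spec >= 1 || sens <= 0) NA_real_ else
    (1 - sens) / (sens * n_pos) + spec / ((1 - spec) * n_neg)
  var_log_neg <- if (spec <= 0 || sens >= 1) 0 else
    sens / ((1 - sens) * n_pos) + (1 - spec) / (spec * n_neg)
  if (is.na(var_log_pos) && is.finite(lr_pos)) var_log_pos <- 0

  list(lr_pos = one_lr(lr_pos, var_log_pos, "lr_pos"),
       lr_neg = one_lr(lr_neg, var_log_neg, "lr_neg"))
}

#' Predictive values implied by sensitivity, specificity and prevalence
#'
#' Bayes' rule for a screening rule: given prevalence \eqn{\pi},
#' \deqn{PPV = \frac{sens\,\pi}{sens\,\pi + (1-spec)(1-\pi)}, \qquad
#'       NPV = \frac{spec\,(1-\pi)}{spec\,(1-\pi) + (1-sens)\,\pi}.}
#'
#' @param sensitivity,specificity,prevalence values strictly inside (0, 1).
#' @return Named numeric vector `c(ppv, npv)`.
#' @examples
#' predictive_values_from_prevalence(0.75, 0.75, 0.30)  # 0.5625, 0.8750
#' @export
predictive_values_from_prevalence <- function(sensitivity, specificity, prevalence) {
  for (v in c(sensitivity = sensitivity, specificity = specificity,
              prevalence = prevalence)) {
    if (!is.numeric(v) || is.na(v) || v <= 0 || v >= 1) {
      stop("boundary error: sensitivity, specificity and prevalence must lie strictly in (0, 1)",
           call. = FALSE)
    }
  }
  ppv <- sensitivity * prevalence /
    (sensitivity * prevalence + (1 - specificity) * (1 - prevalence))
  npv <- specificity * (1 - prevalence) /
    (specificity * (1 - prevalence) + (1 - sensitivity) * prevalence)
  c(ppv = ppv, npv = npv)
}

#' Full accuracy report for a confusion table
#'
#' Convenience wrapper bundling [accuracy_metrics()], [likelihood_ratios()]
#' and (optionally) a precomputed AUC metric into one report.
#'
#' @param ct a [confusion_table()].
#' @param ci_level confidence level.
#' @param lr_ci_scale CI scale for the likelihood ratios.
#' @param auc optional AUC metric list (e.g. `weighted_auc(...)$metric`).
#' @return An `accuracy_report` whose `metrics` may include `lr_pos`,
#'   `lr_neg` and `auc` beyond the four proportions.
#' @export
accuracy_report <- function(ct, ci_level = 0.95,
                            lr_ci_scale = c("natural", "log"), auc = NULL) {
  rep <- accuracy_metrics(ct, ci_level)
  rep$metrics <- c(rep$metrics, likelihood_ratios(ct, ci_level, lr_ci_scale))
  if (!is.null(auc)) rep$metrics$auc <- auc
  rep
}

#' @export
print.accuracy_report <- function(x, digits = 2, ...) {
  cat(sprintf("Diagnostic accuracy (CI level %.0f%%)\n", 100 * x$ci_level))
  for (m in x$metrics) {
    cat(sprintf("  %-12s %5.*f  SE %.*f  CI (%.*f - %.*f)\n",
                m$name, digits, round_half_up(m$estimate, digits),
                digits, round_half_up(m$se, digits),
                digits, round_half_up(m$ci_low, digits),
                digits, round_half_up(m$ci_high, digits)))
  }
  invisible(x)
}

#' Acceptability verdicts for an accuracy report
#'
#' Applies the pre-specified acceptability rules: sensitivity plus
#' specificity of at least 150%; a positive likelihood ratio between 5 and
#' 10 ("acceptable"; above 10 "strong", below 5 "weak"); a negative
#' likelihood ratio between 0.1 and 0.2 ("acceptable"; below 0.1 "strong";
#' 0.2 to 0.5 "informative" — still able to move pre- to post-test
#' probability; above 0.5 "weak"); an AUC in [0.7, 0.8) "acceptable" and
#' at or above 0.8 "excellent" (boundaries belong to the upper band),
#' below 0.7 "poor".
#'
#' @param report an [accuracy_report()]; `lr_pos`/`lr_neg`/`auc` verdicts
#'   are produced when those metrics are present.
#' @return A list with `sens_spec_sum`, `sens_spec_ok`, and the bands
#'   `lr_pos_band`, `lr_neg_band`, `auc_band` (when available).
#' @export
acceptability <- function(report) {
  stopifnot(inherits(report, "accuracy_report"))
  m <- report$metrics
  out <- list()
  sum_ss <- m$sensitivity$estimate + m$specificity$estimate
  out$sens_spec_sum <- sum_ss
  out$sens_spec_ok <- sum_ss >= 1.5
  if (!is.null(m$lr_pos)) {
    lp <- m$lr_pos$estimate
    out$lr_pos_band <- if (lp > 10) "strong" else if (lp >= 5) "acceptable" else "weak"
  }
  if (!is.null(m$lr_neg)) {
    ln <- m$lr_neg$estimate
    out$lr_neg_band <- if (ln < 0.1) "strong" else if (ln <= 0.2) "acceptable"
      else if (ln <= 0.5) "informative" else "weak"
  }
  if (!is.null(m$auc)) {
    a <- m$auc$estimate
    out$auc_band <- if (a >= 0.8) "excellent" else if (a >= 0.7) "acceptable" else "poor"
  }
  out
}
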