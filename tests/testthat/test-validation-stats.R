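published_table <- confusion_table(tp = 599, fp = 197, fn = 265, tn = 1902)

test_that("proportion metrics carry binomial Wald machinery", {
  rep <- accuracy_metrics(published_table)
  m <- rep$metrics
  expect_equal(m$sensitivity$estimate, 599 / 864)
  expect_equal(m$specificity$estimate, 1902 / 2099)
  expect_equal(m$ppv$estimate, 599 / 796)
  expect_equal(m$npv$estimate, 1902 / 2167)
  # CI is estimate +/- z * SE, truncated to [0, 1], and brackets the estimate
  for (nm in names(m)) {
    with(m[[nm]], {
      expect_true(ci_low <= estimate && estimate <= ci_high)
      expect_gte(ci_low, 0); expect_lte(ci_high, 1)
      expect_equal(ci_high - ci_low, 2 * qnorm(0.975) * se, tolerance = 1e-12)
    })
  }
  # a perfect table gives exact metrics with zero uncertainty
  perf <- accuracy_metrics(confusion_table(40, 0, 0, 60))
  for (nm in names(perf$metrics)) {
    expect_equal(perf$metrics[[nm]]$estimate, 1)
    expect_equal(perf$metrics[[nm]]$se, 0)
  }
})

test_that("zero denominators raise undefined-metric errors naming the metric", {
  expect_error(accuracy_metrics(confusion_table(0, 5, 0, 5)), "sensitivity")
  expect_error(accuracy_metrics(confusion_table(5, 0, 5, 0)), "specificity")
  expect_error(likelihood_ratios(confusion_table(0, 5, 0, 5)),
               "both reference classes")
})

test_that("likelihood ratios use the delta method on the log scale", {
  lr <- likelihood_ratios(published_table)
  sens <- 599 / 864; spec <- 1902 / 2099
  expect_equal(lr$lr_pos$estimate, sens / (1 - spec))
  expect_equal(lr$lr_neg$estimate, (1 - sens) / spec)
  # SE = LR * sqrt(Var(ln LR)) with the standard 2x2 variance
  var_log_pos <- (1 - sens) / 599 + spec / 197
  expect_equal(lr$lr_pos$se, lr$lr_pos$estimate * sqrt(var_log_pos))
  # natural-scale Wald interval is symmetric about the estimate
  expect_equal(lr$lr_pos$ci_high - lr$lr_pos$estimate,
               lr$lr_pos$estimate - lr$lr_pos$ci_low, tolerance = 1e-12)
  # log-scale option shifts the interval but keeps the estimate and SE
  lr_log <- likelihood_ratios(published_table, ci_scale = "log")
  expect_equal(lr_log$lr_pos$estimate, lr$lr_pos$estimate)
  expect_equal(lr_log$lr_pos$se, lr$lr_pos$se)
  expect_gt(lr_log$lr_pos$ci_low, 0)
  expect_gt(lr_log$lr_pos$ci_high, lr_log$lr_pos$estimate)
  # an uninformative test has both ratios equal to one
  unif <- likelihood_ratios(confusion_table(25, 25, 25, 25))
  expect_equal(unif$lr_pos$estimate, 1)
  expect_equal(unif$lr_neg$estimate, 1)
  # perfect specificity signals an infinite LR+ instead of crashing
  inf <- likelihood_ratios(confusion_table(10, 0, 10, 10))
  expect_identical(inf$lr_pos$estimate, Inf)
})

test_that("delta-method LR standard errors agree with a multinomial bootstrap", {
  set.seed(20548)
  n <- 2963
  probs <- c(599, 197, 265, 1902) / n
  draws <- stats::rmultinom(10000, n, probs)
  sens_b <- draws[1, ] / (draws[1, ] + draws[3, ])
  spec_b <- draws[4, ] / (draws[4, ] + draws[2, ])
  boot_se_pos <- sd(sens_b / (1 - spec_b))
  boot_se_neg <- sd((1 - sens_b) / spec_b)
  lr <- likelihood_ratios(published_table)
  expect_lt(abs(lr$lr_pos$se - boot_se_pos) / boot_se_pos, 0.10)
  expect_lt(abs(lr$lr_neg$se - boot_se_neg) / boot_se_neg, 0.10)
})

test_that("likelihood ratios are invariant to prevalence", {
  # same sens/spec, different prevalence (positive rows scaled by 2)
  t1 <- confusion_table(80, 30, 20, 70)
  t2 <- confusion_table(160, 30, 40, 70)
  lr1 <- likelihood_ratios(t1)
  lr2 <- likelihood_ratios(t2)
  expect_equal(lr1$lr_pos$estimate, lr2$lr_pos$estimate, tolerance = 1e-12)
  expect_equal(lr1$lr_neg$estimate, lr2$lr_neg$estimate, tolerance = 1e-12)
})

test_that("prevalence-based predictive values follow Bayes' rule", {
  pv <- predictive_values_from_prevalence(0.75, 0.75, 0.30)
  expect_equal(unname(pv), c(0.5625, 0.875))
  # symmetric prevalence: PPV = NPV = the shared accuracy
  for (s in c(0.6, 0.8, 0.95)) {
    pv <- predictive_values_from_prevalence(s, s, 0.5)
    expect_equal(unname(pv), c(s, s), tolerance = 1e-12)
  }
  # Bayes consistency: plugging in the sample prevalence recovers the
  # direct PPV/NPV of the table
  ct <- published_table
  rep <- accuracy_metrics(ct)
  prev <- (ct$tp + ct$fn) / (ct$tp + ct$fp + ct$fn + ct$tn)
  pv <- predictive_values_from_prevalence(rep$metrics$sensitivity$estimate,
                                          rep$metrics$specificity$estimate,
                                          prev)
  expect_equal(pv[["ppv"]], rep$metrics$ppv$estimate, tolerance = 1e-12)
  expect_equal(pv[["npv"]], rep$metrics$npv$estimate, tolerance = 1e-12)
  expect_error(predictive_values_from_prevalence(0.75, 0.75, 0), "boundary error")
  expect_error(predictive_values_from_prevalence(0.75, 0.75, 1), "boundary error")
})

test_that("stratified negative sampling has exact design properties", {
  # census fraction: everyone verified with weight one
  coh <- generate_cohort(demo_params(600, seed = 41))
  dec <- evaluate_bpa(coh)
  census <- sample_negatives(coh, dec, sampling_design(1, seed = 1))
  expect_setequal(census$visit_id, coh$visit_id)
  expect_true(all(census$weight == 1))

  # weights over a stratum's sample sum exactly to its negative population
  ver <- sample_negatives(coh, dec, sampling_design(0.25, seed = 2))
  tab <- attr(ver, "stratum_table")
  for (i in seq_len(nrow(tab))) {
    s <- tab$stratum[i]
    w <- ver$weight[!ver$triggered & ver$race_ethnicity == s]
    expect_equal(length(w), tab$n_sampled[i])
    expect_equal(sum(w), tab$n_negative[i], tolerance = 1e-12)
  }
  # positives are always fully verified with weight one
  expect_equal(sum(ver$triggered), sum(dec$triggered))
  expect_true(all(ver$weight[ver$triggered] == 1))

  # determinism under the design seed
  ver2 <- sample_negatives(coh, dec, sampling_design(0.25, seed = 2))
  expect_identical(ver, ver2)
})

test_that("a 10% stratified draw of 2,167 negatives verifies 221 of them", {
  strata_neg <- c(hispanic = 545, white_nh = 176, black_nh = 1260,
                  asian_nh = 61, other_nh = 96, unknown = 29)
  n_pos <- 796
  records <- data.frame(
    visit_id = sprintf("V%04d", seq_len(n_pos + sum(strata_neg))),
    race_ethnicity = c(rep("black_nh", n_pos),
                       rep(names(strata_neg), strata_neg)),
    stringsAsFactors = FALSE)
  decisions <- data.frame(visit_id = records$visit_id,
                          triggered = c(rep(TRUE, n_pos),
                                        rep(FALSE, sum(strata_neg))))
  # half-up per-stratum rounding at a fraction of ~0.102 verifies 221 of
  # the 2,167 negatives (the exact rounding rule of the original draw is
  # not recoverable; 0.1019 realizes the same verified count)
  ver <- sample_negatives(records, decisions,
                          sampling_design(0.1019, seed = 7))
  expect_equal(sum(!ver$triggered), 221)
  expect_equal(sum(ver$weight[!ver$triggered]), 2167, tolerance = 1e-12)
  expect_equal(sum(ver$weight), 2963, tolerance = 1e-12)
})

test_that("a tiny stratum that rounds to an empty sample is a design error", {
  records <- data.frame(visit_id = c("a", "b", "c"),
                        race_ethnicity = c("x", "x", "y"))
  decisions <- data.frame(visit_id = records$visit_id, triggered = FALSE)
  expect_error(sample_negatives(records, decisions, sampling_design(0.1)),
               "design error")
})

test_that("the weighted confusion table extrapolates the verified sample", {
  # unit weights, four pairs covering the four outcomes
  dec <- data.frame(visit_id = letters[1:4],
                    triggered = c(TRUE, TRUE, FALSE, FALSE))
  lab <- data.frame(visit_id = letters[1:4],
                    should_trigger = c(TRUE, FALSE, TRUE, FALSE))
  ct <- build_confusion(dec, lab)
  expect_equal(unlist(unclass(ct)), c(tp = 1, fp = 1, fn = 1, tn = 1))

  # doubling every weight doubles every cell, leaving proportions unchanged
  w <- data.frame(visit_id = letters[1:4], weight = 2)
  ct2 <- build_confusion(dec, lab, w)
  expect_equal(unlist(unclass(ct2)), 2 * unlist(unclass(ct)))
  r1 <- accuracy_metrics(ct); r2 <- accuracy_metrics(ct2)
  expect_equal(r1$metrics$sensitivity$estimate, r2$metrics$sensitivity$estimate)

  # all-unit explicit weights reduce exactly to the unweighted table
  w1 <- data.frame(visit_id = letters[1:4], weight = 1)
  expect_equal(build_confusion(dec, lab, w1), ct)

  expect_error(build_confusion(dec, lab[1:2, ],
                               data.frame(visit_id = letters[1:4], weight = 1)),
               "alignment error")
})

test_that("weighted row totals reproduce the cohort margins exactly", {
  p <- calibrate_to_cells(c(599, 197, 265, 1902),
                          cohort_params(n_patients = 2963, p_lab_ordered = 1,
                                        seed = 12))
  coh <- generate_cohort(p)
  dec <- evaluate_bpa(coh)
  lab <- review_chart(coh)
  ver <- sample_negatives(coh, dec, sampling_design(0.10, seed = 5))
  ct <- build_confusion(dec, lab, ver[, c("visit_id", "weight")])
  expect_equal(ct$tp + ct$fp, sum(dec$triggered), tolerance = 1e-9)
  expect_equal(ct$fn + ct$tn, sum(!dec$triggered), tolerance = 1e-9)
  expect_equal(ct$tp + ct$fp + ct$fn + ct$tn, 2963, tolerance = 1e-9)
})

test_that("acceptability verdicts implement the pre-specified bands", {
  rep <- accuracy_report(published_table)
  rep$metrics$auc <- list(name = "auc", estimate = 0.74, se = 0.01,
                          ci_low = 0.72, ci_high = 0.77, ci_level = 0.95)
  v <- acceptability(rep)
  expect_true(v$sens_spec_ok)
  expect_equal(round_half_up(v$sens_spec_sum, 2), 1.60)
  expect_identical(v$lr_pos_band, "acceptable")
  expect_identical(v$lr_neg_band, "informative")
  expect_identical(v$auc_band, "acceptable")

  # a 0.7 + 0.7 rule fails the 150% bar
  weak <- accuracy_report(confusion_table(70, 30, 30, 70))
  expect_false(acceptability(weak)$sens_spec_ok)

  # band boundaries: 0.8 is excellent, 0.7 acceptable; LR boundaries inclusive
  for (case in list(c(0.80, NA), c(0.70, NA))) {
    rep$metrics$auc$estimate <- case[1]
    band <- acceptability(rep)$auc_band
    expect_identical(band, if (case[1] >= 0.8) "excellent" else "acceptable")
  }
  rep$metrics$lr_pos$estimate <- 10; rep$metrics$lr_neg$estimate <- 0.2
  v <- acceptability(rep)
  expect_identical(v$lr_pos_band, "acceptable")
  expect_identical(v$lr_neg_band, "acceptable")
  rep$metrics$lr_pos$estimate <- 12; rep$metrics$lr_neg$estimate <- 0.05
  v <- acceptability(rep)
  expect_identical(v$lr_pos_band, "strong")
  expect_identical(v$lr_neg_band, "strong")
  rep$metrics$lr_pos$estimate <- 3; rep$metrics$lr_neg$estimate <- 0.7
  v <- acceptability(rep)
  expect_identical(v$lr_pos_band, "weak")
  expect_identical(v$lr_neg_band, "weak")
})
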