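test_that("the response rule is a boundary-inclusive 50% reduction", {
  expect_identical(label_response(30, 15), "responder")
  expect_identical(label_response(30, 16), "nonresponder")
  expect_identical(label_response(c(40, 20), c(10, 11)),
                   c("responder", "nonresponder"))
  expect_error(label_response(0, 0),
               class = "eegresponse_error_undefined_reduction")
})

test_that("confusion metrics reproduce the published escitalopram-cohort values", {
  # 56 responders (37 detected), 69 nonresponders (43 detected)
  m <- confusion_metrics(list(TP = 37, FN = 19, TN = 43, FP = 26))
  expect_equal(round(100 * m$sensitivity, 1), 66.1)
  expect_equal(round(100 * m$specificity, 1), 62.3)
  expect_equal(round(100 * m$balanced_accuracy, 1), 64.2)
})

test_that("confusion metrics reproduce the published sertraline-cohort values", {
  # 51 responders (30 detected), 54 nonresponders (37 detected)
  m <- confusion_metrics(list(TP = 30, FN = 21, TN = 37, FP = 17))
  expect_equal(round(100 * m$sensitivity, 1), 58.8)
  expect_equal(round(100 * m$specificity, 1), 68.5)
  expect_equal(round(100 * m$balanced_accuracy, 1), 63.7)
  # placebo arm: balanced accuracy from the printed percentage pair
  # (reported with half-away-from-zero rounding: 48.65 -> 48.7)
  expect_equal(round_away(balanced_accuracy(50.0, 47.3), 1), 48.7)
  expect_equal(round_away(63.65, 1), 63.7)
  expect_equal(round_away(-0.25, 1), -0.3)
  # degenerate and perfect cases
  expect_error(confusion_metrics(list(TP = 0, FN = 0, TN = 5, FP = 0)),
               class = "eegresponse_error_undefined_metric")
  perf <- confusion_metrics(list(TP = 5, FN = 0, TN = 5, FP = 0))
  expect_equal(as.numeric(perf), c(1, 1, 1))
})

test_that("normal-approximation intervals match the published sensitivity CIs", {
  ci <- proportion_ci(37, 56, method = "normal")
  expect_equal(round(100 * ci$lower, 1), 53.7)
  expect_equal(round(100 * ci$upper, 1), 78.5)
  ci2 <- proportion_ci(30, 51, method = "normal")
  expect_equal(round(100 * ci2$lower, 1), 45.3)
  expect_equal(round(100 * ci2$upper, 1), 72.3)
})

test_that("Clopper-Pearson endpoints follow the exact beta closed forms", {
  ci <- proportion_ci(3, 3, method = "clopper_pearson")
  expect_equal(ci$lower, 0.025^(1 / 3), tolerance = 1e-9)
  expect_equal(ci$upper, 1)
  expect_equal(proportion_ci(0, 10, method = "clopper_pearson")$lower, 0)
  expect_equal(proportion_ci(0, 10, method = "normal")$lower, 0)
  expect_error(proportion_ci(5, 10, level = 1.5),
               class = "eegresponse_error_parameter")
  expect_error(proportion_ci(11, 10), class = "eegresponse_error_parameter")
})

test_that("99% intervals contain 95% intervals for both methods", {
  for (m in c("normal", "clopper_pearson")) {
    for (case in list(c(3, 10), c(25, 40), c(55, 56))) {
      lo <- proportion_ci(case[1], case[2], 0.95, m)
      hi <- proportion_ci(case[1], case[2], 0.99, m)
      expect_lte(hi$lower, lo$lower)
      expect_gte(hi$upper, lo$upper)
    }
  }
})

test_that("Clopper-Pearson coverage is at least nominal (exact enumeration)", {
  for (p in c(0.1, 0.3, 0.5, 0.8)) {
    for (n in c(10, 25)) {
      covered <- vapply(0:n, function(x) {
        ci <- proportion_ci(x, n, 0.95, "clopper_pearson")
        ci$lower <= p && p <= ci$upper
      }, TRUE)
      expect_gte(sum(stats::dbinom(0:n, n, p)[covered]), 0.95)
    }
  }
})

test_that("the sex-distribution chi-square matches the published comparison", {
  # females/males: 78/47 escitalopram cohort, 72/33 sertraline cohort
  res <- chi_square_2x2(rbind(c(78, 47), c(72, 33)))
  expect_equal(round(res$statistic, 2), 0.96)
  expect_equal(round(res$p_value, 2), 0.33)
  expect_equal(res$df, 1)
})

test_that("chi-square degenerate and perfect-association cases", {
  expect_equal(chi_square_2x2(rbind(c(10, 20), c(20, 40)))$statistic, 0)
  expect_equal(chi_square_2x2(rbind(c(10, 0), c(0, 10)))$statistic, 20)
  expect_error(chi_square_2x2(rbind(c(0, 0), c(5, 5))),
               class = "eegresponse_error_degenerate_table")
  # the corrected variant is available and more conservative
  un <- chi_square_2x2(rbind(c(78, 47), c(72, 33)))
  yates <- chi_square_2x2(rbind(c(78, 47), c(72, 33)), correct = TRUE)
  expect_lt(yates$statistic, un$statistic)
})

test_that("the summary-statistic Welch test matches the published age comparison", {
  res <- welch_t_from_summary(36.4, 13.0, 125, 38.4, 13.8, 105)
  expect_equal(round(res$p_value, 2), 0.26)
  same <- welch_t_from_summary(10, 2, 50, 10, 2, 50)
  expect_equal(same$t, 0); expect_equal(same$p_value, 1)
  closer <- welch_t_from_summary(10, 2, 50, 10.5, 2, 50)
  farther <- welch_t_from_summary(10, 2, 50, 12, 2, 50)
  expect_gt(closer$p_value, farther$p_value)
})

test_that("mean CIs reproduce the published age intervals", {
  ci <- mean_ci(36.4, 13.0, 125)
  expect_equal(round(ci$lower, 1), 34.1)
  expect_equal(round(ci$upper, 1), 38.7)
  ci2 <- mean_ci(38.4, 13.8, 105)
  expect_equal(round(ci2$lower, 1), 35.8)
  expect_equal(round(ci2$upper, 1), 41.0)
  flat <- mean_ci(5, 0, 10)
  expect_equal(c(flat$lower, flat$upper), c(5, 5))
})

test_that("summarize_predictions reports both interval methods consistently", {
  truth <- rep(c("responder", "nonresponder"), c(20, 30))
  est <- truth
  est[c(1:6, 21:29)] <- rev(est[c(1:6, 21:29)])  # some errors both ways
  s <- summarize_predictions(truth, est)
  expect_identical(s$metric,
                   c("sensitivity", "specificity", "balanced_accuracy"))
  expect_true(all(s$lower <= s$estimate & s$estimate <= s$upper))
  expect_true(all(s$lower_exact[1:2] <= s$estimate[1:2]))
  expect_equal(s$n, c(20, 30, 50))
})
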