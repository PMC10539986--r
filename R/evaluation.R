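#' Label treatment response from depression-scale scores
#'
#' A subject is a responder when the clinician-rated severity score drops by
#' 50% or more from baseline to week 8 (boundary inclusive). Works for
#' MADRS- or HDRS-style scales; the rule is a proportion of baseline, so
#' units cancel.
#'
#' @param score_week0 Baseline score(s), must be > 0.
#' @param score_week8 Week-8 score(s).
#' @return Character vector: `"responder"` or `"nonresponder"`.
#' @export
label_response <- function(score_week0, score_week8) {
  if (any(score_week0 <= 0))
    stop_input("Baseline score must be > 0; percent reduction is undefined.",
               "undefined_reduction")
  ifelse((score_week0 - score_week8) / score_week0 >= 0.5,
         "responder", "nonresponder")
}

#' Confusion counts from truth/prediction vectors
#'
#' Responder status is the positive outcome.
#'
#' @param truth,estimate Label vectors.
#' @param positive The positive class label.
#' @return A named list with `TP`, `FN`, `TN`, `FP`.
#' @export
confusion_counts <- function(truth, estimate, positive = "responder") {
  truth <- as.character(truth); estimate <- as.character(estimate)
  list(TP = sum(truth == positive & estimate == positive),
       FN = sum(truth == positive & estimate != positive),
       TN = sum(truth != positive & estimate != positive),
       FP = sum(truth != positive & estimate == positive))
}

#' Sensitivity, specificity and balanced accuracy from confusion counts
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), balanced accuracy =
#' their mean -- robust to class imbalance.
#'
#' @param counts Named list or vector with `TP`, `FN`, `TN`, `FP`.
#' @return Tibble with `sensitivity`, `specificity`, `balanced_accuracy`
#'   (proportions).
#' @export
confusion_metrics <- function(counts) {
  tp <- counts[["TP"]]; fn <- counts[["FN"]]
  tn <- counts[["TN"]]; fp <- counts[["FP"]]
  if (tp + fn < 1 || tn + fp < 1)
    stop_input("Both classes must be present to compute sensitivity and specificity.",
               "undefined_metric")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  tibble::tibble(sensitivity = sens, specificity = spec,
                 balanced_accuracy = (sens + spec) / 2)
}

#' Balanced accuracy from a sensitivity/specificity pair
#'
#' @param sensitivity,specificity Proportions (or percentages -- the mean is
#'   scale-equivariant).
#' @return Their arithmetic mean.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}

#' Round half away from zero
#'
#' Reporting-style rounding: exact halves round away from zero (48.65 ->
#' 48.7 at one decimal), unlike [round()]'s round-half-to-even. Used when
#' formatting percentages for reports.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_away <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

#' Binomial proportion confidence interval
#'
#' `method = "normal"`: Wald interval `p +/- z * sqrt(p(1-p)/n)`, clipped to
#' `[0, 1]`. `method = "clopper_pearson"`: exact interval from beta
#' quantiles, `lower = qbeta(a/2, x, n-x+1)`, `upper = qbeta(1-a/2, x+1,
#' n-x)`, with the conventional 0 and 1 endpoints at `x = 0` and `x = n`.
#'
#' @param successes Number of successes `x`.
#' @param n Number of trials.
#' @param level Confidence level in (0, 1), default 0.95.
#' @param method `"normal"` or `"clopper_pearson"`.
#' @return Tibble with `estimate`, `lower`, `upper`, `method`, `n`.
#' @export
proportion_ci <- function(successes, n, level = 0.95,
                          method = c("normal", "clopper_pearson")) {
  method <- match.arg(method)
  if (level <= 0 || level >= 1)
    stop_input("`level` must be in (0, 1).", "parameter")
  if (successes < 0 || successes > n || n < 1)
    stop_input("Need 0 <= successes <= n and n >= 1.", "parameter")
  x <- successes
  p <- x / n
  a <- 1 - level
  if (method == "normal") {
    z <- qnorm(1 - a / 2)
    half <- z * sqrt(p * (1 - p) / n)
    lower <- max(0, p - half); upper <- min(1, p + half)
  } else {
    lower <- if (x == 0) 0 else qbeta(a / 2, x, n - x + 1)
    upper <- if (x == n) 1 else qbeta(1 - a / 2, x + 1, n - x)
  }
  tibble::tibble(estimate = p, lower = lower, upper = upper,
                 method = method, n = n)
}

#' Pearson chi-square test for a 2 x 2 table
#'
#' Without continuity correction by default (set `correct = TRUE` for the
#' Yates-corrected variant). Degrees of freedom are 1.
#'
#' @param table 2 x 2 numeric matrix of counts.
#' @param correct Apply Yates continuity correction?
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)))
    stop_input("`table` must be 2 x 2.", "parameter")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected <= 0))
    stop_input("A zero marginal makes the chi-square test degenerate.",
               "degenerate_table")
  ht <- stats::chisq.test(table, correct = correct)
  tibble::tibble(statistic = unname(ht$statistic), df = 1,
                 p_value = unname(ht$p.value))
}

#' Welch two-sample t test from summary statistics
#'
#' Unequal-variance t statistic and Satterthwaite degrees of freedom
#' computed from group means, SDs and sizes (no raw data needed).
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return Tibble with `t`, `df`, `p_value` (two-sided).
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0 || n1 < 2 || n2 < 2)
    stop_input("Need positive SDs and n >= 2 per group.", "parameter")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble::tibble(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Normal-theory confidence interval for a mean from summary statistics
#'
#' `mean +/- z * sd / sqrt(n)` with the standard normal quantile for the
#' requested level.
#'
#' @param mean,sd,n Summary statistics.
#' @param level Confidence level, default 0.95.
#' @return Tibble with `mean`, `lower`, `upper`.
#' @export
mean_ci <- function(mean, sd, n, level = 0.95) {
  if (sd < 0 || n < 2) stop_input("Need sd >= 0 and n >= 2.", "parameter")
  z <- qnorm(1 - (1 - level) / 2)
  half <- z * sd / sqrt(n)
  tibble::tibble(mean = mean, lower = mean - half, upper = mean + half)
}

#' Summarize predictions into metrics with confidence intervals
#'
#' Computes sensitivity, specificity and balanced accuracy with 95%
#' intervals by both the normal approximation and the Clopper-Pearson exact
#' method (both are reported; the balanced-accuracy interval uses the
#' normal approximation with the variance of the mean of the two
#' proportions, and has no exact counterpart).
#'
#' @param truth,estimate Label vectors.
#' @param positive The positive class label.
#' @param level Confidence level.
#' @return Tibble: one row per metric with `estimate`, `lower`/`upper`
#'   (normal), `lower_exact`/`upper_exact` (Clopper-Pearson), `n`.
#' @export
summarize_predictions <- function(truth, estimate, positive = "responder",
                                  level = 0.95) {
  cc <- confusion_counts(truth, estimate, positive)
  m <- confusion_metrics(cc)
  n_pos <- cc$TP + cc$FN; n_neg <- cc$TN + cc$FP
  sens_n <- proportion_ci(cc$TP, n_pos, level, "normal")
  sens_e <- proportion_ci(cc$TP, n_pos, level, "clopper_pearson")
  spec_n <- proportion_ci(cc$TN, n_neg, level, "normal")
  spec_e <- proportion_ci(cc$TN, n_neg, level, "clopper_pearson")
  z <- qnorm(1 - (1 - level) / 2)
  ba_se <- sqrt(m$sensitivity * (1 - m$sensitivity) / n_pos / 4 +
                m$specificity * (1 - m$specificity) / n_neg / 4)
  tibble::tibble(
    metric = c("sensitivity", "specificity", "balanced_accuracy"),
    estimate = c(m$sensitivity, m$specificity, m$balanced_accuracy),
    lower = c(sens_n$lower, spec_n$lower,
              max(0, m$balanced_accuracy - z * ba_se)),
    upper = c(sens_n$upper, spec_n$upper,
              min(1, m$balanced_accuracy + z * ba_se)),
    lower_exact = c(sens_e$lower, spec_e$lower, NA),
    upper_exact = c(sens_e$upper, spec_e$upper, NA),
    n = c(n_pos, n_neg, n_pos + n_neg))
}
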