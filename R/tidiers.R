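#' Tidy a cross-validation result
#'
#' One row per predicted subject: truth, prediction and the hyperparameters
#' selected in that subject's outer fold.
#'
#' @param x An `eeg_cv_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.eeg_cv_result <- function(x, ...) x$predictions

#' Glance at a cross-validation result
#'
#' A one-row summary: scheme, subject count, and the three performance
#' metrics with their normal-approximation 95% bounds.
#'
#' @param x An `eeg_cv_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.eeg_cv_result <- function(x, ...) {
  s <- x$summary
  get <- function(metric, col) s[[col]][s$metric == metric]
  tibble::tibble(
    scheme = x$scheme,
    n = nrow(x$predictions),
    sensitivity = get("sensitivity", "estimate"),
    specificity = get("specificity", "estimate"),
    balanced_accuracy = get("balanced_accuracy", "estimate"),
    balanced_accuracy_lower = get("balanced_accuracy", "lower"),
    balanced_accuracy_upper = get("balanced_accuracy", "upper"))
}

#' Tidy a trained kNN model
#'
#' The inner-selection grid scores, with the chosen row flagged.
#'
#' @param x An `eeg_knn`.
#' @param ... Unused.
#' @return A tibble with `k`, `metric`, `balanced_accuracy`, `chosen`.
#' @export
tidy.eeg_knn <- function(x, ...) {
  dplyr::mutate(x$inner_scores,
                chosen = .data$k == x$k & .data$metric == x$metric)
}

#' Glance at a trained kNN model
#'
#' @param x An `eeg_knn`.
#' @param ... Unused.
#' @return A one-row tibble: chosen hyperparameters, training size, feature
#'   count and inner LOO balanced accuracy.
#' @export
glance.eeg_knn <- function(x, ...) {
  inner <- x$inner_scores$balanced_accuracy[
    x$inner_scores$k == x$k & x$inner_scores$metric == x$metric]
  tibble::tibble(k = x$k, metric = x$metric,
                 n_train = nrow(x$train),
                 n_features = length(x$feature_names),
                 inner_balanced_accuracy = inner)
}

#' Tidy a permutation-importance result
#'
#' @param x An `eeg_importance`.
#' @param ... Unused.
#' @return The underlying tibble (feature, mean and SD of the
#'   balanced-accuracy reduction, repeat count).
#' @export
tidy.eeg_importance <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("feature", "mean_reduction",
                                 "sd_reduction", "repeats")])
}
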