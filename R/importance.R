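#' Permutation feature importance
#'
#' Measures each feature's contribution as the mean drop in balanced
#' accuracy when that feature's values are shuffled across subjects,
#' breaking its association with the labels while preserving its marginal
#' distribution. The baseline score is computed once; each
#' feature x repeat permutation draws from an independent seeded stream, so
#' results are reproducible and independent of evaluation order. Negative
#' mean reductions (the model improving under shuffling) are possible for
#' uninformative features and are retained in the raw output.
#'
#' @param evaluate Function `(X, y) -> balanced accuracy` (a proportion).
#'   Must be deterministic given its inputs.
#' @param X Feature matrix (`eeg_feature_matrix` tibble or numeric matrix).
#' @param y Labels, one per row.
#' @param repeats Permutation repeats per feature (default 100).
#' @param seed Master seed for the permutation streams.
#' @return An object of class `eeg_importance`: tibble with `feature`,
#'   `mean_reduction`, `sd_reduction`, `repeats`; attributes `baseline` and
#'   `seed`.
#' @export
permutation_importance <- function(evaluate, X, y, repeats = 100, seed = 1) {
  X <- resolve_feature_values(X)
  if (nrow(X) < 2)
    stop_input("Permutation importance is undefined for fewer than 2 subjects.",
               "parameter")
  if (repeats < 1) stop_input("`repeats` must be >= 1.", "parameter")
  baseline <- evaluate(X, y)
  n <- nrow(X)
  reductions <- matrix(NA_real_, ncol(X), repeats)
  for (f in seq_len(ncol(X))) {
    for (rep_i in seq_len(repeats)) {
      perm <- with_local_seed(derive_seed(seed, f, rep_i), sample.int(n))
      Xp <- X
      Xp[, f] <- X[perm, f]
      reductions[f, rep_i] <- baseline - evaluate(Xp, y)
    }
  }
  out <- tibble::tibble(
    feature = colnames(X),
    mean_reduction = rowMeans(reductions),
    sd_reduction = apply(reductions, 1, sd),
    repeats = repeats)
  attr(out, "baseline") <- baseline
  attr(out, "seed") <- seed
  class(out) <- c("eeg_importance", class(out))
  out
}

# classify a feature name into the four display blocks
feature_block <- function(feature) {
  asym <- startsWith(feature, "asym_")
  is_mse <- grepl("mse_(fine|medium|coarse)$", feature)
  dplyr::case_when(
    asym & is_mse ~ "MSE asymmetry",
    asym ~ "Power asymmetry",
    is_mse ~ "MSE",
    TRUE ~ "Power")
}

#' Rendering table for a feature-importance heatmap
#'
#' Prepares the raw importance values for display in the conventional
#' four-block layout (power, power asymmetry, MSE, MSE asymmetry): negative
#' mean reductions are floored at 0 -- a feature whose shuffling *improves*
#' the model carries no usable information -- and features are annotated
#' with their region/pair and feature-band labels. Raw (possibly negative)
#' values remain available in the `eeg_importance` object itself.
#'
#' @param importance An `eeg_importance` from [permutation_importance()].
#' @return Tibble with `feature`, `block`, `location`, `measure`,
#'   `mean_reduction` (floored at 0).
#' @export
importance_rendering <- function(importance) {
  stopifnot(inherits(importance, "eeg_importance"))
  feat <- importance$feature
  measure <- sub("^.*?_(delta|theta|alpha|beta|gamma|mse_fine|mse_medium|mse_coarse)$",
                 "\\1", feat)
  location <- mapply(function(f, m) {
    loc <- sub(paste0("_", m, "$"), "", f)
    sub("^asym_", "", loc)
  }, feat, measure, USE.NAMES = FALSE)
  tibble::tibble(
    feature = feat,
    block = feature_block(feat),
    location = location,
    measure = measure,
    mean_reduction = pmax(importance$mean_reduction, 0))
}
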