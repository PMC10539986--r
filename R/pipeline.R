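prepare_cohort_labels <- function(cohort, min_baseline_score = NULL) {
  req <- c("subject_id", "score_week0", "score_week8")
  missing_cols <- setdiff(req, names(cohort))
  if (length(missing_cols))
    stop_input(paste0("Cohort table lacks column(s): ",
                      paste(missing_cols, collapse = ", ")), "metadata")
  if (!is.null(min_baseline_score))
    cohort <- dplyr::filter(cohort, .data$score_week0 >= min_baseline_score)
  dplyr::mutate(cohort,
                responder = label_response(.data$score_week0,
                                           .data$score_week8))
}

align_features_labels <- function(features, cohort) {
  common <- intersect(features$subject_id, cohort$subject_id)
  if (length(common) < 2)
    stop_input("Fewer than 2 subjects have both features and clinical scores.",
               "pipeline")
  features <- features[match(common, features$subject_id), ]
  cohort <- cohort[match(common, cohort$subject_id), ]
  list(features = features, cohort = cohort)
}

#' Internal validation: feature extraction + nested cross-validation
#'
#' Runs the full internal-validation pipeline on one cohort: response
#' labelling from the score table (with an optional minimum-baseline-severity
#' filter), per-subject feature extraction with quality-based exclusions,
#' and nested cross-validation (leave-one-out by default, or stratified
#' k-fold). If the cohort table has a `site` column, metrics are also
#' reported per site.
#'
#' @param recordings Named list of `eeg_recording` objects.
#' @param cohort Tibble with `subject_id`, `score_week0`, `score_week8` and
#'   optionally `site`.
#' @param map,cleaning,spectral,mse Stage configurations (see
#'   [region_map()], [cleaning_config()], [spectral_config()],
#'   [mse_config()]).
#' @param grid An [hyperparam_grid()].
#' @param scheme `"loo"` or `"kfold"`.
#' @param k_outer Outer fold count when `scheme = "kfold"`.
#' @param seed Seed for fold assignment (k-fold only).
#' @param min_baseline_score Optional minimum baseline score; subjects below
#'   it are excluded before modelling.
#' @return An `eeg_validation_report`: list with `cv` (the
#'   [nested_loocv()]/[nested_kfold()] result), `metrics`, `per_site`,
#'   `features`, `exclusions` and `provenance`.
#' @export
run_internal_validation <- function(recordings, cohort,
                                    map = default_region_map(),
                                    cleaning = cleaning_config(),
                                    spectral = spectral_config(),
                                    mse = mse_config(),
                                    grid = hyperparam_grid(),
                                    scheme = c("loo", "kfold"),
                                    k_outer = 10, seed = 1,
                                    min_baseline_score = NULL) {
  scheme <- match.arg(scheme)
  cohort <- prepare_cohort_labels(cohort, min_baseline_score)
  features <- build_feature_matrix(recordings[names(recordings) %in%
                                                cohort$subject_id],
                                   map, cleaning, spectral, mse)
  al <- align_features_labels(features, cohort)
  y <- al$cohort$responder
  cv <- if (scheme == "loo") nested_loocv(al$features, y, grid)
        else nested_kfold(al$features, y, grid, k_outer = k_outer, seed = seed)
  per_site <- NULL
  if ("site" %in% names(al$cohort)) {
    preds <- dplyr::left_join(cv$predictions,
                              al$cohort[, c("subject_id", "site")],
                              by = "subject_id")
    per_site <- dplyr::group_modify(
      dplyr::group_by(preds, .data$site),
      ~ summarize_predictions(.x$truth, .x$estimate))
    per_site <- dplyr::ungroup(per_site)
  }
  structure(list(
    cv = cv, metrics = cv$summary, per_site = per_site,
    features = al$features,
    exclusions = attr(features, "exclusions"),
    provenance = list(
      seed = seed, scheme = scheme,
      n_subjects = nrow(al$features),
      config_hash = rlang::hash(list(map, cleaning, spectral, mse, grid)))),
    class = "eeg_validation_report")
}

#' @export
print.eeg_validation_report <- function(x, ...) {
  cat("<eeg_validation_report>", x$provenance$n_subjects, "subjects,",
      x$cv$scheme, "\n")
  print(x$metrics)
  invisible(x)
}

#' External validation: train on one cohort, predict another
#'
#' Trains the final leave-one-out-tuned kNN model on the training cohort and
#' evaluates it on an independent test cohort. Both cohorts are given as
#' `list(recordings = ..., cohort = ...)` (features are extracted with the
#' shared configuration) or `list(features = ..., cohort = ...)` if features
#' are already extracted. Overlapping subject ids between train and test
#' trigger a leakage warning -- resubstitution estimates are optimistic.
#'
#' @param train,test Cohort lists as described above.
#' @inheritParams run_internal_validation
#' @return An `eeg_external_report`: list with `model`, `predictions`
#'   (tibble), `metrics`, `exclusions` and `provenance`.
#' @export
run_external_validation <- function(train, test,
                                    map = default_region_map(),
                                    cleaning = cleaning_config(),
                                    spectral = spectral_config(),
                                    mse = mse_config(),
                                    grid = hyperparam_grid(),
                                    min_baseline_score = NULL) {
  get_features <- function(ch) {
    if (!is.null(ch$features)) return(ch$features)
    build_feature_matrix(ch$recordings, map, cleaning, spectral, mse)
  }
  tr_cohort <- prepare_cohort_labels(train$cohort)
  te_cohort <- prepare_cohort_labels(test$cohort, min_baseline_score)
  tr <- align_features_labels(get_features(train), tr_cohort)
  te <- align_features_labels(get_features(test), te_cohort)
  overlap <- intersect(tr$features$subject_id, te$features$subject_id)
  if (length(overlap))
    warn(paste0("Train and test cohorts share ", length(overlap),
                " subject id(s); metrics will be optimistically biased."),
         class = "eegresponse_warning_leakage")
  model <- train_final(tr$features, tr$cohort$responder, grid)
  est <- predict_external(model, te$features)
  predictions <- tibble::tibble(subject_id = te$features$subject_id,
                                truth = te$cohort$responder,
                                estimate = est)
  metrics <- summarize_predictions(predictions$truth, predictions$estimate)
  per_site <- NULL
  if ("site" %in% names(te$cohort)) {
    preds <- dplyr::left_join(predictions,
                              te$cohort[, c("subject_id", "site")],
                              by = "subject_id")
    per_site <- dplyr::ungroup(dplyr::group_modify(
      dplyr::group_by(preds, .data$site),
      ~ summarize_predictions(.x$truth, .x$estimate)))
  }
  structure(list(model = model, predictions = predictions,
                 metrics = metrics, per_site = per_site,
                 train_features = tr$features, train_labels = tr$cohort$responder,
                 test_features = te$features, test_labels = te$cohort$responder,
                 provenance = list(
                   n_train = nrow(tr$features), n_test = nrow(te$features),
                   config_hash = rlang::hash(list(map, cleaning, spectral,
                                                  mse, grid)))),
            class = "eeg_external_report")
}

#' @export
print.eeg_external_report <- function(x, ...) {
  cat("<eeg_external_report>", x$provenance$n_train, "training /",
      x$provenance$n_test, "test subjects; k =", x$model$k,
      "metric =", x$model$metric, "\n")
  print(x$metrics)
  invisible(x)
}

#' Leave-one-out evaluator under a fixed trained model
#'
#' Returns a function `(X, y) -> balanced accuracy` that predicts every
#' subject by its k nearest neighbours among the *other* subjects, reusing
#' the trained model's standardization and hyperparameters (nothing is
#' refitted). This is the evaluation procedure permutation importance uses
#' for the internal-validation setting.
#'
#' @param model An `eeg_knn` from [train_final()].
#' @return A function suitable as the `evaluate` argument of
#'   [permutation_importance()].
#' @export
loo_fixed_model_evaluate <- function(model) {
  function(X, y) {
    Xs <- standardize_apply(model$standardizer, resolve_feature_values(X))
    y <- as.character(y)
    D <- self_distance(Xs, model$metric)
    diag(D) <- Inf
    n <- nrow(Xs)
    est <- vapply(seq_len(n), function(i) {
      ord <- order(D[i, ], seq_len(n))
      vote_labels(y[ord][-n], model$k, model$positive)
    }, "")
    balanced_accuracy_of(y, est, model$positive)
  }
}

#' Permutation feature importance for a validation setting
#'
#' Computes permutation importance for either the internal or the external
#' validation of a trained model. The model (standardization +
#' hyperparameters) is trained once and reused; each feature column of the
#' evaluation set is then shuffled `repeats` times and the mean reduction in
#' balanced accuracy recorded. For `validation = "internal"` the evaluation
#' procedure is leave-one-out prediction of the training cohort under the
#' fixed model; for `"external"` it is prediction of the test cohort.
#'
#' @param external_report An `eeg_external_report` from
#'   [run_external_validation()] (carries the trained model and both
#'   cohorts' features).
#' @param validation `"internal"` or `"external"`.
#' @param repeats Permutation repeats per feature, default 100.
#' @param seed Master seed for the permutation streams.
#' @return A list of class `eeg_importance_report`: `importance` (raw, may
#'   contain negative reductions) and `rendering` (floored at 0, grouped
#'   into the four display blocks).
#' @export
run_importance <- function(external_report,
                           validation = c("internal", "external"),
                           repeats = 100, seed = 1) {
  stopifnot(inherits(external_report, "eeg_external_report"))
  validation <- match.arg(validation)
  model <- external_report$model
  if (validation == "internal") {
    evaluate <- loo_fixed_model_evaluate(model)
    X <- external_report$train_features
    y <- external_report$train_labels
  } else {
    evaluate <- function(X, y)
      balanced_accuracy_of(as.character(y), predict_external(model, X),
                           model$positive)
    X <- external_report$test_features
    y <- external_report$test_labels
  }
  imp <- permutation_importance(evaluate, X, y, repeats = repeats, seed = seed)
  structure(list(importance = imp, rendering = importance_rendering(imp),
                 validation = validation),
            class = "eeg_importance_report")
}

#' @export
print.eeg_importance_report <- function(x, ...) {
  cat("<eeg_importance_report>", x$validation, "validation;",
      nrow(x$importance), "features,", x$importance$repeats[1], "repeats\n")
  top <- dplyr::arrange(x$importance, dplyr::desc(.data$mean_reduction))
  print(utils::head(top, 5))
  invisible(x)
}
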