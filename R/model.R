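#' Hyperparameter grid for the kNN classifier
#'
#' The two tuned hyperparameters are the neighbour count `k` and the
#' distance metric. Defaults use odd `k` in 1..25 (odd values cannot
#' produce vote ties in a two-class problem) and the euclidean, manhattan
#' and correlation metrics; chebyshev is also available.
#'
#' @param k_values Integer vector of neighbour counts.
#' @param metrics Character vector of distance metric names.
#' @return An object of class `eeg_hyperparam_grid`.
#' @export
hyperparam_grid <- function(k_values = seq(1, 25, by = 2),
                            metrics = c("euclidean", "manhattan",
                                        "correlation")) {
  if (!length(k_values) || !length(metrics))
    stop_input("Grid must contain at least one k and one metric.", "parameter")
  if (any(k_values < 1))
    stop_input("All k values must be >= 1.", "parameter")
  metrics <- match.arg(metrics,
                       c("euclidean", "manhattan", "chebyshev", "correlation"),
                       several.ok = TRUE)
  structure(list(k_values = as.integer(k_values), metrics = metrics),
            class = "eeg_hyperparam_grid")
}

#' Fit / apply feature standardization
#'
#' `standardize_fit()` learns per-feature centre (mean) and spread (SD) from
#' training rows only; features with zero spread are dropped with a warning
#' and recorded so the model manifest shrinks consistently.
#' `standardize_apply()` applies training parameters to any matrix, aligning
#' columns by name.
#'
#' @param X Numeric matrix (rows = subjects) with column names.
#' @return `standardize_fit()`: an `eeg_standardizer`;
#'   `standardize_apply()`: a standardized matrix restricted to retained
#'   features.
#' @export
standardize_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2)
    stop_input("Standardization needs at least 2 training rows.", "parameter")
  ctr <- colMeans(X)
  spr <- apply(X, 2, sd)
  drop <- spr < 1e-12
  if (any(drop))
    warn(paste0("Dropping constant feature(s): ",
                paste(colnames(X)[drop], collapse = ", ")),
         class = "eegresponse_warning_constant_feature")
  structure(list(center = ctr[!drop], scale = spr[!drop],
                 features = colnames(X)[!drop],
                 dropped = colnames(X)[drop]),
            class = "eeg_standardizer")
}

#' @rdname standardize_fit
#' @param params An `eeg_standardizer` from `standardize_fit()`.
#' @export
standardize_apply <- function(params, X) {
  X <- as.matrix(X)
  missing_cols <- setdiff(params$features, colnames(X))
  if (length(missing_cols))
    stop_input(paste0("Matrix lacks feature column(s): ",
                      paste(missing_cols, collapse = ", ")), "manifest")
  X <- X[, params$features, drop = FALSE]
  sweep(sweep(X, 2, params$center), 2, params$scale, `/`)
}

# full self-distance matrix; stats::dist does euclidean/manhattan/chebyshev
# in C, correlation falls back to cor()
self_distance <- function(X, metric) {
  if (metric == "correlation") return(1 - cor(t(X)))
  method <- c(euclidean = "euclidean", manhattan = "manhattan",
              chebyshev = "maximum")[[metric]]
  as.matrix(stats::dist(X, method = method))
}

pairwise_distance <- function(A, B, metric) {
  A <- as.matrix(A); B <- as.matrix(B)
  switch(metric,
    euclidean = {
      d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
      sqrt(pmax(d2, 0))
    },
    manhattan = vapply(seq_len(nrow(B)), function(j)
      rowSums(abs(A - matrix(B[j, ], nrow(A), ncol(A), byrow = TRUE))),
      numeric(nrow(A))),
    chebyshev = vapply(seq_len(nrow(B)), function(j)
      apply(abs(A - matrix(B[j, ], nrow(A), ncol(A), byrow = TRUE)), 1, max),
      numeric(nrow(A))),
    correlation = 1 - cor(t(A), t(B)),
    stop_input(paste0("Unknown distance metric: ", metric), "parameter")
  )
}

check_two_classes <- function(y) {
  lv <- unique(as.character(y))
  if (length(lv) != 2L)
    stop_input(sprintf("Need exactly 2 classes in the labels, found %d.",
                       length(lv)), "stratification")
  invisible(lv)
}

# majority vote with deterministic tie-breaking: distance ties resolved by
# lower training index, vote ties (possible for even k) by the single
# nearest neighbour's label
vote_labels <- function(sorted_labels, k, positive) {
  votes_pos <- sum(sorted_labels[seq_len(k)] == positive)
  if (2 * votes_pos > k) return(positive)
  if (2 * votes_pos < k) return(setdiff(unique(sorted_labels), positive)[1])
  sorted_labels[1]
}

#' k-nearest-neighbour prediction
#'
#' Classifies each test row by majority vote among its `k` nearest training
#' rows under the chosen metric. Fully deterministic: distance ties are
#' broken by lower training row index and vote ties (even `k`) by the label
#' of the single nearest neighbour.
#'
#' @param train Numeric matrix of training rows (already standardized).
#' @param labels Class labels, one per training row (2 classes).
#' @param k Neighbour count, `1 <= k <= nrow(train) - 1` recommended;
#'   must not exceed `nrow(train)`.
#' @param metric One of `"euclidean"`, `"manhattan"`, `"chebyshev"`,
#'   `"correlation"`.
#' @param test Numeric matrix of rows to classify.
#' @return Character vector of predicted labels.
#' @export
knn_predict <- function(train, labels, k, metric, test) {
  train <- as.matrix(train); test <- as.matrix(test)
  labels <- as.character(labels)
  if (k > nrow(train))
    stop_input("k cannot exceed the number of training rows.", "parameter")
  lv <- check_two_classes(labels)
  positive <- if ("responder" %in% lv) "responder" else lv[1]
  D <- pairwise_distance(train, test, metric)
  vapply(seq_len(ncol(D)), function(j) {
    ord <- order(D[, j], seq_len(nrow(D)))
    vote_labels(labels[ord], k, positive)
  }, "")
}

balanced_accuracy_of <- function(truth, estimate, positive) {
  pos <- truth == positive
  sens <- mean(estimate[pos] == positive)
  spec <- mean(estimate[!pos] != positive)
  (sens + spec) / 2
}

#' Inner-loop hyperparameter selection
#'
#' Scores every `(k, metric)` grid point by leave-one-out balanced accuracy
#' on the (already standardized) training data and returns the best. Ties
#' are broken by smaller `k`, then by metric order in the grid, so selection
#' is deterministic.
#'
#' @param X Standardized numeric training matrix.
#' @param y Training labels (2 classes, both present).
#' @param grid An [hyperparam_grid()].
#' @return A list with `k`, `metric` and `scores` (a tibble of the full
#'   inner grid search).
#' @export
inner_select <- function(X, y, grid = hyperparam_grid()) {
  X <- as.matrix(X); y <- as.character(y)
  lv <- check_two_classes(y)
  positive <- if ("responder" %in% lv) "responder" else lv[1]
  n <- nrow(X)
  ks <- grid$k_values[grid$k_values <= n - 1L]
  if (!length(ks))
    stop_input("No grid k value fits the inner training size.", "parameter")
  all_k <- integer(0); all_metric <- character(0); all_ba <- numeric(0)
  for (metric in grid$metrics) {
    D <- self_distance(X, metric)
    diag(D) <- Inf
    # per held-out row: training labels sorted by distance, then cumulative
    # positive votes give the prediction for every k at once
    negative <- setdiff(lv, positive)
    pred <- matrix("", n, length(ks))
    for (i in seq_len(n)) {
      ord <- order(D[i, ], seq_len(n))
      is_pos <- (y[ord] == positive)[-n]  # drop the Inf self entry (last)
      cum_pos <- cumsum(is_pos)[ks]
      pr <- rep(negative, length(ks))
      pr[2 * cum_pos > ks] <- positive
      tie <- 2 * cum_pos == ks            # even k: nearest neighbour decides
      if (any(tie)) pr[tie] <- if (is_pos[1]) positive else negative
      pred[i, ] <- pr
    }
    all_k <- c(all_k, ks)
    all_metric <- c(all_metric, rep(metric, length(ks)))
    all_ba <- c(all_ba, vapply(seq_along(ks), function(kidx)
      balanced_accuracy_of(y, pred[, kidx], positive), 1))
  }
  best <- order(-all_ba, all_k, match(all_metric, grid$metrics))[1]
  list(k = all_k[best], metric = all_metric[best],
       scores = tibble::tibble(k = all_k, metric = all_metric,
                               balanced_accuracy = all_ba))
}

new_cv_result <- function(predictions, positive, grid, scheme) {
  structure(list(predictions = predictions,
                 summary = summarize_predictions(predictions$truth,
                                                 predictions$estimate,
                                                 positive),
                 positive = positive, grid = grid, scheme = scheme),
            class = "eeg_cv_result")
}

#' @export
print.eeg_cv_result <- function(x, ...) {
  cat("<eeg_cv_result>", x$scheme, "with", nrow(x$predictions), "predictions\n")
  print(x$summary)
  invisible(x)
}

nested_cv_engine <- function(X, y, grid, folds, scheme) {
  X <- as.matrix(X); y <- as.character(y)
  lv <- check_two_classes(y)
  positive <- if ("responder" %in% lv) "responder" else lv[1]
  ids <- rownames(X) %||% sprintf("row%03d", seq_len(nrow(X)))
  preds <- list()
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(nrow(X)), test_idx)
    ytr <- y[train_idx]
    if (length(unique(ytr)) < 2L)
      stop_input("A training fold contains a single class; stratification failed.",
                 "stratification")
    std <- standardize_fit(X[train_idx, , drop = FALSE])
    Xtr <- standardize_apply(std, X[train_idx, , drop = FALSE])
    hp <- inner_select(Xtr, ytr, grid)
    Xte <- standardize_apply(std, X[test_idx, , drop = FALSE])
    est <- knn_predict(Xtr, ytr, hp$k, hp$metric, Xte)
    preds[[f]] <- tibble::tibble(
      subject_id = ids[test_idx], fold = f,
      truth = y[test_idx], estimate = est,
      k = hp$k, metric = hp$metric)
  }
  predictions <- dplyr::bind_rows(preds)
  predictions <- predictions[match(ids, predictions$subject_id), ]
  new_cv_result(predictions, positive, grid, scheme)
}

#' Nested leave-one-out cross-validation
#'
#' For every held-out subject: standardization is fitted and hyperparameters
#' are selected (by inner leave-one-out) on the remaining subjects only,
#' then a kNN model predicts the held-out subject. Each subject is predicted
#' exactly once; no information from the held-out subject leaks into
#' scaling or tuning. No final model is produced -- each fold may select
#' different hyperparameters.
#'
#' @param X Feature matrix: an `eeg_feature_matrix` tibble or a numeric
#'   matrix with feature column names.
#' @param y Class labels, one per row (2 classes).
#' @param grid An [hyperparam_grid()].
#' @param seed Unused (the procedure is deterministic); accepted for
#'   interface symmetry with [nested_kfold()].
#' @return An `eeg_cv_result`: per-fold predictions and chosen
#'   hyperparameters plus summary metrics with confidence intervals.
#' @export
nested_loocv <- function(X, y, grid = hyperparam_grid(), seed = NULL) {
  X <- resolve_feature_values(X)
  folds <- as.list(seq_len(nrow(X)))
  nested_cv_engine(X, y, grid, folds, scheme = "nested LOOCV")
}

#' Nested stratified k-fold cross-validation
#'
#' As [nested_loocv()] but with `k_outer` stratified outer folds; fold
#' assignment shuffles subjects within each class under a seed derived from
#' `seed`, then deals them round-robin, so the same seed always gives the
#' same folds. With `k_outer = nrow(X)` the per-subject predictions are
#' identical to nested LOOCV.
#'
#' @inheritParams nested_loocv
#' @param k_outer Number of outer folds (>= 2).
#' @param seed Integer seed controlling fold assignment.
#' @return An `eeg_cv_result`.
#' @export
nested_kfold <- function(X, y, grid = hyperparam_grid(), k_outer, seed = 1) {
  X <- resolve_feature_values(X)
  if (k_outer < 2 || k_outer > nrow(X))
    stop_input("`k_outer` must be between 2 and the number of subjects.",
               "parameter")
  y <- as.character(y)
  fold_of <- integer(nrow(X))
  with_local_seed(derive_seed(seed, k_outer), {
    offset <- 0L   # classes continue the deal so folds stay balanced
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold_of[idx] <- ((offset + seq_along(idx) - 1L) %% k_outer) + 1L
      offset <- offset + length(idx)
    }
  })
  folds <- split(seq_len(nrow(X)), fold_of)
  nested_cv_engine(X, y, grid, folds,
                   scheme = sprintf("nested %d-fold CV", k_outer))
}

#' Train the final kNN model on a full cohort
#'
#' Selects one set of hyperparameters by leave-one-out over the whole
#' training cohort, fits standardization on the whole cohort, and retains
#' all training rows, yielding a single model that can classify new data by
#' its nearest neighbours in the training set.
#'
#' @inheritParams nested_loocv
#' @return An object of class `eeg_knn`: standardizer, standardized
#'   training matrix, labels, chosen hyperparameters, feature manifest and
#'   the inner selection scores.
#' @export
train_final <- function(X, y, grid = hyperparam_grid()) {
  X <- resolve_feature_values(X)
  y <- as.character(y)
  lv <- check_two_classes(y)
  std <- standardize_fit(X)
  Xs <- standardize_apply(std, X)
  hp <- inner_select(Xs, y, grid)
  structure(list(standardizer = std, train = Xs, labels = y,
                 k = hp$k, metric = hp$metric,
                 feature_names = std$features,
                 positive = if ("responder" %in% lv) "responder" else lv[1],
                 inner_scores = hp$scores),
            class = "eeg_knn")
}

#' @export
print.eeg_knn <- function(x, ...) {
  cat(sprintf("<eeg_knn> k = %d, metric = %s, %d training subjects, %d features\n",
              x$k, x$metric, nrow(x$train), length(x$feature_names)))
  invisible(x)
}

#' Predict an external cohort with a trained model
#'
#' Standardizes the external feature matrix with the training parameters
#' (never refitted) and classifies each row by its k nearest training
#' neighbours. Columns are aligned by name; a missing or extra feature is a
#' manifest error listing the discrepancies.
#'
#' @param model An `eeg_knn` from [train_final()].
#' @param X_ext External feature matrix (`eeg_feature_matrix` or numeric
#'   matrix with feature column names).
#' @return Character vector of predicted labels, one per external row.
#' @export
predict_external <- function(model, X_ext) {
  stopifnot(inherits(model, "eeg_knn"))
  X_ext <- resolve_feature_values(X_ext)
  extra <- setdiff(colnames(X_ext),
                   c(model$feature_names, model$standardizer$dropped))
  missing_cols <- setdiff(model$feature_names, colnames(X_ext))
  if (length(missing_cols) || length(extra))
    stop_input(paste0(
      "External features do not match the model manifest.",
      if (length(missing_cols)) paste0(" Missing: ",
                                       paste(missing_cols, collapse = ", ")),
      if (length(extra)) paste0(" Unexpected: ",
                                paste(extra, collapse = ", "))),
      "manifest")
  Xs <- standardize_apply(model$standardizer, X_ext)
  knn_predict(model$train, model$labels, model$k, model$metric, Xs)
}

#' @export
predict.eeg_knn <- function(object, newdata, ...) predict_external(object, newdata)

resolve_feature_values <- function(X) {
  if (inherits(X, "eeg_feature_matrix") ||
      (is.data.frame(X) && "subject_id" %in% names(X)))
    return(feature_matrix_values(X))
  as.matrix(X)
}
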