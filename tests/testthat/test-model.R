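test_that("standardization centres and scales on training data only", {
  fc <- feature_cohort(n = 20, p = 6, seed = 2)
  std <- standardize_fit(fc$X)
  Xs <- standardize_apply(std, fc$X)
  expect_equal(unname(colMeans(Xs)), rep(0, 6), tolerance = 1e-9)
  expect_equal(unname(apply(Xs, 2, sd)), rep(1, 6), tolerance = 1e-9)
  centre_row <- matrix(std$center, 1, dimnames = list(NULL, std$features))
  expect_equal(unname(standardize_apply(std, centre_row)[1, ]), rep(0, 6))
})

test_that("constant features are dropped with a warning and recorded", {
  X <- cbind(feature_cohort(n = 10, p = 3, seed = 3)$X, f_const = 5)
  expect_warning(std <- standardize_fit(X),
                 class = "eegresponse_warning_constant_feature")
  expect_identical(std$dropped, "f_const")
  expect_equal(ncol(standardize_apply(std, X)), 3)
})

test_that("kNN matches the exhaustive-search oracle on small instances", {
  set.seed(20)
  for (case in 1:8) {
    n <- sample(6:30, 1)
    p <- sample(2:5, 1)
    train <- matrix(rnorm(n * p), n, p)
    labels <- sample(c("responder", "nonresponder"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("responder", "nonresponder")
    test <- matrix(rnorm(3 * p), 3, p)
    for (metric in c("euclidean", "manhattan", "chebyshev", "correlation")) {
      for (k in unique(c(1, 2, 3, sample(n - 1, 1)))) {
        expect_identical(
          knn_predict(train, labels, k, metric, test),
          unname(knn_oracle(train, labels, k, metric, test)),
          info = sprintf("n=%d p=%d metric=%s k=%d", n, p, metric, k))
      }
    }
  }
})

test_that("kNN honours its deterministic contracts", {
  train <- matrix(c(0, 1, 10), 3, 1)
  labels <- c("A", "A", "B")
  # k=3 majority around 0.5 is A
  expect_identical(knn_predict(train, labels, 3, "euclidean",
                               matrix(0.5)), "A")
  # k=1 on an exact duplicate returns that row's label
  expect_identical(knn_predict(train, labels, 1, "euclidean",
                               matrix(10)), "B")
  # even k vote tie: the nearest neighbour decides
  train2 <- matrix(c(0, 3), 2, 1); labels2 <- c("A", "B")
  expect_identical(knn_predict(train2, labels2, 2, "euclidean",
                               matrix(1)), "A")
  # distance tie: lower training index wins
  train3 <- matrix(c(-1, 1), 2, 1); labels3 <- c("A", "B")
  expect_identical(knn_predict(train3, labels3, 1, "euclidean",
                               matrix(0)), "A")
  expect_error(knn_predict(train, labels, 2, "mahalanobis", matrix(0)),
               class = "eegresponse_error_parameter")
})

test_that("inner selection maximizes inner balanced accuracy with documented tie rules", {
  # single grid point: returned as-is
  fc <- feature_cohort(n = 16, p = 4, effect = 0, seed = 4)
  Xs <- standardize_apply(standardize_fit(fc$X), fc$X)
  one <- hyperparam_grid(k_values = 7, metrics = "manhattan")
  sel <- inner_select(Xs, fc$y, one)
  expect_equal(sel$k, 7L); expect_equal(sel$metric, "manhattan")

  # well-separated classes: perfect inner score, ties resolved to smallest k
  fc2 <- feature_cohort(n = 20, p = 3, n_informative = 3, effect = 8, seed = 5)
  Xs2 <- standardize_apply(standardize_fit(fc2$X), fc2$X)
  sel2 <- inner_select(Xs2, fc2$y, hyperparam_grid(k_values = c(1, 3, 5)))
  best <- max(sel2$scores$balanced_accuracy)
  expect_equal(best, 1)
  expect_equal(sel2$k, 1L)
  expect_equal(sel2$metric, "euclidean")   # first metric in grid order

  expect_error(inner_select(Xs2, rep("responder", 20), hyperparam_grid()),
               class = "eegresponse_error_stratification")
})

test_that("nested k-fold with k = n reproduces nested LOOCV exactly", {
  fc <- feature_cohort(n = 24, p = 10, effect = 1.5, seed = 6)
  g <- grid_small()
  loo <- nested_loocv(fc$X, fc$y, g)
  kf <- nested_kfold(fc$X, fc$y, g, k_outer = 24, seed = 3)
  a <- tidy(loo)[c("subject_id", "estimate", "k", "metric")]
  b <- tidy(kf)[c("subject_id", "estimate", "k", "metric")]
  expect_identical(a[order(a$subject_id), ], b[order(b$subject_id), ])
  # every subject predicted exactly once
  expect_setequal(tidy(loo)$subject_id, rownames(fc$X))
  expect_equal(nrow(tidy(loo)), 24)
})

test_that("nested k-fold is deterministic in its seed and stratifies folds", {
  fc <- feature_cohort(n = 30, p = 8, effect = 1, seed = 7)
  g <- grid_small()
  a <- nested_kfold(fc$X, fc$y, g, k_outer = 5, seed = 11)
  b <- nested_kfold(fc$X, fc$y, g, k_outer = 5, seed = 11)
  expect_identical(tidy(a), tidy(b))
  c_ <- nested_kfold(fc$X, fc$y, g, k_outer = 5, seed = 12)
  expect_false(identical(tidy(a)$fold, tidy(c_)$fold))
  folds <- split(fc$y, tidy(a)$fold[match(rownames(fc$X),
                                          tidy(a)$subject_id)])
  expect_true(all(vapply(folds, function(f)
    length(unique(f)) == 2L, TRUE)))
})

test_that("the outer test subject never influences fold training decisions", {
  fc <- feature_cohort(n = 20, p = 6, effect = 2, seed = 8)
  g <- grid_small()
  base <- nested_loocv(fc$X, fc$y, g)
  X_out <- fc$X
  X_out[1, ] <- X_out[1, ] + 1e4        # extreme outlier as held-out subject
  out <- nested_loocv(X_out, fc$y, g)
  # fold 1 trains on subjects 2..n, identical in both runs: its selected
  # hyperparameters cannot change, however extreme the held-out subject
  expect_identical(tidy(base)[1, c("k", "metric")],
                   tidy(out)[1, c("k", "metric")])
  # and the fold-training standardization parameters are literally unchanged
  expect_identical(standardize_fit(fc$X[-1, ]), standardize_fit(X_out[-1, ]))
})

test_that("a strongly separated cohort is recovered by nested LOOCV", {
  fc <- feature_cohort(n = 30, p = 10, n_informative = 4, effect = 4, seed = 9)
  cv <- nested_loocv(fc$X, fc$y, grid_small())
  expect_gte(glance(cv)$balanced_accuracy, 0.9)
})

test_that("train_final yields a reusable deterministic model", {
  fc <- feature_cohort(n = 26, p = 8, n_informative = 3, effect = 3, seed = 10)
  g <- grid_small()
  m1 <- train_final(fc$X, fc$y, g)
  m2 <- train_final(fc$X, fc$y, g)
  expect_identical(m1[c("k", "metric")], m2[c("k", "metric")])
  expect_identical(m1$train, m2$train)
  one <- train_final(fc$X, fc$y, hyperparam_grid(k_values = 5,
                                                 metrics = "correlation"))
  expect_equal(one$k, 5L); expect_equal(one$metric, "correlation")
  # duplicate of a training row under k=1 comes back with its own label
  m_k1 <- train_final(fc$X, fc$y, hyperparam_grid(k_values = 1,
                                                  metrics = "euclidean"))
  expect_identical(predict_external(m_k1, fc$X[3, , drop = FALSE]),
                   fc$y[3])
})

test_that("external prediction aligns columns by name and checks the manifest", {
  fc <- feature_cohort(n = 26, p = 8, n_informative = 3, effect = 3, seed = 11)
  model <- train_final(fc$X, fc$y, grid_small())
  ext <- feature_cohort(n = 10, p = 8, n_informative = 3, effect = 3,
                        seed = 12)$X
  straight <- predict_external(model, ext)
  shuffled_cols <- ext[, sample(ncol(ext))]
  expect_identical(predict_external(model, shuffled_cols), straight)
  bad <- ext; colnames(bad)[1] <- "not_a_feature"
  err <- expect_error(predict_external(model, bad),
                      class = "eegresponse_error_manifest")
  expect_match(conditionMessage(err), "f01")
  expect_match(conditionMessage(err), "not_a_feature")
})

test_that("tidiers expose predictions, hyperparameters and summaries", {
  fc <- feature_cohort(n = 16, p = 5, effect = 2, seed = 13)
  cv <- nested_loocv(fc$X, fc$y, grid_small())
  td <- tidy(cv)
  expect_true(all(c("subject_id", "truth", "estimate", "k", "metric")
                  %in% names(td)))
  gl <- glance(cv)
  expect_equal(nrow(gl), 1)
  expect_true(gl$balanced_accuracy >= 0 && gl$balanced_accuracy <= 1)
  model <- train_final(fc$X, fc$y, grid_small())
  expect_equal(sum(tidy(model)$chosen), 1)
  expect_equal(glance(model)$n_features, 5)
})
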