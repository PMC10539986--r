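# shared fixtures: small, fast study objects built in code

# reduced entropy scale range for structural tests where only the plumbing
# (not the 1-70 curve) matters; keeps single-subject extraction ~100x faster
mse_fast <- function() {
  mse_config(scales = 1:6,
             timescale_bands = list(fine = c(1, 2), medium = c(3, 4),
                                    coarse = c(5, 6)))
}

grid_small <- function() hyperparam_grid(k_values = c(1, 3, 5),
                                         metrics = c("euclidean", "manhattan"))

quick_spec <- function(n_resp = 3, n_non = 3, ...) {
  synthetic_cohort_spec(n_resp, n_non, sfreq = 128, duration = 60, ...)
}

quick_recording <- function(seed = 1, n_channels = 2, sfreq = 128,
                            duration = 10, labels = NULL) {
  set.seed(seed)
  labels <- labels %||% paste0("C", seq_len(n_channels))
  recording(matrix(rnorm(n_channels * sfreq * duration, sd = 10),
                   nrow = n_channels),
            labels, sfreq, subject_id = paste0("fix", seed))
}

# synthetic tabular cohort for model-level tests: `n_informative` features
# carry a class shift of `effect` SD, the rest are noise
feature_cohort <- function(n = 40, p = 20, n_informative = 1, effect = 2,
                           seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("S%03d", seq_len(n)),
                              sprintf("f%02d", seq_len(p))))
  y <- rep(c("responder", "nonresponder"), length.out = n)
  if (n_informative > 0)
    X[y == "responder", seq_len(n_informative)] <-
      X[y == "responder", seq_len(n_informative)] + effect
  list(X = X, y = y)
}

`%||%` <- rlang::`%||%`

# independent O(N^2) pair-counting oracle for sample entropy
sampen_oracle <- function(x, m, r) {
  nt <- length(x) - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  c(A = A, B = B)
}

# independent exhaustive-search kNN oracle with the same deterministic
# tie-breaking contract (distance ties by index, vote ties by nearest label)
knn_oracle <- function(train, labels, k, metric, test) {
  dist_fn <- switch(metric,
    euclidean = function(a, b) sqrt(sum((a - b)^2)),
    manhattan = function(a, b) sum(abs(a - b)),
    chebyshev = function(a, b) max(abs(a - b)),
    correlation = function(a, b) 1 - cor(a, b))
  apply(test, 1, function(tr) {
    d <- apply(train, 1, dist_fn, b = tr)
    ord <- order(d, seq_along(d))
    top <- labels[ord][1:k]
    tab <- table(top)
    if (length(tab) > 1 && tab[1] == tab[2]) labels[ord][1]
    else names(tab)[which.max(tab)]
  })
}
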