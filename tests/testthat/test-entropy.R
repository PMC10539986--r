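test_that("coarse-graining computes block means", {
  expect_identical(coarse_grain(c(1, 2, 3, 4, 5, 6), 2), c(1.5, 3.5, 5.5))
  expect_identical(coarse_grain(c(1, 2, 3, 4, 5, 6), 3), c(2, 5))
  expect_identical(coarse_grain(c(1, 2, 3, 4, 5, 6, 7), 3), c(2, 5))  # remainder dropped
  x <- rnorm(10)
  expect_identical(coarse_grain(x, 1), x)
  expect_error(coarse_grain(x, 0), class = "eegresponse_error_parameter")
})

test_that("perfectly regular series have zero sample entropy", {
  expect_equal(sample_entropy(rep(2.5, 100), 2, 0.1), 0)
  expect_equal(sample_entropy(rep(c(1, -1), 50), 2, 0.3), 0)
})

test_that("sample entropy matches the brute-force pair-counting oracle exactly", {
  set.seed(10)
  for (case in 1:6) {
    n <- sample(50:500, 1)
    x <- switch(1 + case %% 3,
                rnorm(n),
                cumsum(rnorm(n)),                       # smooth random walk
                sin(seq_len(n) / 5) + rnorm(n, sd = 0.3))
    m <- sample(1:3, 1)
    r <- runif(1, 0.1, 0.3) * sd(x)
    oracle <- sampen_oracle(x, m, r)
    cnt <- eegresponse:::sampen_counts_cpp(x, m, r)
    expect_identical(unname(oracle), as.numeric(cnt))
    if (oracle["B"] > 0 && oracle["A"] > 0)
      expect_equal(sample_entropy(x, m, r),
                   -log(oracle["A"] / oracle["B"]), ignore_attr = TRUE)
  }
})

test_that("white-noise sample entropy approaches its analytic value", {
  set.seed(11)
  x <- rnorm(30000)
  analytic <- -log(2 * pnorm(0.15 / sqrt(2)) - 1)    # ~2.4714
  expect_equal(sample_entropy(x, 2, 0.15 * sd(x)), analytic, tolerance = 0.1 / analytic)
})

test_that("degenerate match counts use the documented sentinels", {
  # B > 0 but no (m+1)-matches: capped at log(B + 1)
  x <- c(0, 10, 0.05, 20, 0.1, 30)
  cnt <- eegresponse:::sampen_counts_cpp(x, 1, 0.2)
  expect_equal(as.numeric(cnt), c(0, 3))
  expect_equal(sample_entropy(x, 1, 0.2), log(4))
  # B = 0: undefined
  expect_true(is.na(sample_entropy(c(0, 100, 200, 300, 400), 1, 1)))
  expect_error(sample_entropy(rnorm(100), 2, 0),
               class = "eegresponse_error_parameter")
})

test_that("entropy with SD-proportional tolerance is amplitude invariant", {
  set.seed(12)
  x <- matrix(rnorm(2 * 2000), 2)
  cfg <- mse_config(scales = 1:10,
                    timescale_bands = list(fine = c(1, 4), medium = c(5, 7),
                                           coarse = c(8, 10)))
  a <- mse_curve(x, 128, cfg)
  b <- mse_curve(x * 57.3, 128, cfg)
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("white noise entropy declines across scales; 1/f noise stays flatter", {
  set.seed(13)
  n <- 7500
  white <- rnorm(n)
  pink <- eegresponse:::one_over_f_noise(n, 250, 1)
  cfg <- mse_config()
  cw <- mse_curve(matrix(white, 1), 250, cfg)[1, ]
  cp <- mse_curve(matrix(pink, 1), 250, cfg)[1, ]
  expect_lt(cor(seq_len(70), cw, method = "spearman"), -0.9)
  drop_white <- mean(cw[1:20]) - mean(cw[36:70])
  drop_pink <- mean(cp[1:20]) - mean(cp[36:70])
  expect_lt(abs(drop_pink), abs(drop_white))
})

test_that("white noise is more irregular than a matched-variance sinusoid at fine scales", {
  set.seed(14)
  hits <- 0
  for (i in 1:10) {
    w <- rnorm(2000)
    s <- sqrt(2) * sin(2 * pi * 10 * seq_len(2000) / 128 + runif(1, 0, 2 * pi))
    ew <- sample_entropy(w, 2, 0.15 * sd(w))
    es <- sample_entropy(s, 2, 0.15 * sd(s))
    hits <- hits + (ew > es)
  }
  expect_gte(hits, 9)
})

test_that("band averages follow the documented arithmetic and exclusion rules", {
  cfg <- mse_config()
  const <- mse_band_average(rep(1.7, 70), cfg)
  expect_equal(const$entropy, rep(1.7, 3))
  ramp <- mse_band_average(as.numeric(1:70), cfg)
  expect_equal(ramp$entropy, c(10.5, 28, 53))
  holed <- as.numeric(1:70); holed[70] <- NA
  expect_equal(mse_band_average(holed, cfg)$entropy[3], mean(36:69))
  all_na <- as.numeric(1:70); all_na[36:70] <- NA
  expect_error(mse_band_average(all_na, cfg),
               class = "eegresponse_error_feature_quality")
})

test_that("mse configuration validates its partition", {
  expect_error(mse_config(scales = 2:10), class = "eegresponse_error_parameter")
  expect_error(mse_config(scales = 1:30), class = "eegresponse_error_parameter")
  expect_error(mse_config(r = 0), class = "eegresponse_error_parameter")
})
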