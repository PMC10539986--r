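make_channel_features <- function(values) {
  # values: named list channel -> numeric(8)
  dplyr::bind_rows(purrr::imap(values, function(v, ch)
    tibble::tibble(channel = ch,
                   !!!stats::setNames(as.list(v),
                                      eegresponse:::feature_order))))
}

test_that("region averaging is the arithmetic mean over member channels", {
  cf <- make_channel_features(list(A = rep(0.2, 8), B = rep(0.4, 8),
                                   C = 1:8))
  rf <- region_average(cf, list(r1 = c(1, 2), r2 = 3))
  expect_equal(as.numeric(rf[1, eegresponse:::feature_order]), rep(0.3, 8))
  expect_equal(as.numeric(rf[2, eegresponse:::feature_order]), as.numeric(1:8))
  # permuting channels within a region changes nothing
  rf2 <- region_average(cf, list(r1 = c(2, 1), r2 = 3))
  expect_equal(rf, rf2)
  expect_error(region_average(cf, list(r1 = integer(0))),
               class = "eegresponse_error_montage")
})

test_that("asymmetry features divide left by right with a zero guard", {
  cf <- make_channel_features(list(L = rep(0.4, 8), R = rep(0.2, 8)))
  rf <- region_average(cf, list(left = 1, right = 2))
  af <- asymmetry_features(rf, list(c("left", "right")))
  expect_equal(as.numeric(af[1, eegresponse:::feature_order]), rep(2, 8))

  sym <- asymmetry_features(region_average(cf, list(left = 1, right = 1)),
                            list(c("left", "right")))
  expect_equal(as.numeric(sym[1, eegresponse:::feature_order]), rep(1, 8))

  cf0 <- make_channel_features(list(L = rep(0.4, 8), R = rep(0, 8)))
  rf0 <- region_average(cf0, list(left = 1, right = 2))
  expect_error(asymmetry_features(rf0, list(c("left", "right"))),
               class = "eegresponse_error_division_guard")
})

test_that("the assembled vector has 152 named entries: 112 region + 40 asymmetry", {
  nm <- feature_names()
  expect_length(nm, 152)
  expect_equal(sum(!startsWith(nm, "asym_")), 14 * 8)
  expect_equal(sum(startsWith(nm, "asym_")), 5 * 8)
  expect_false(anyDuplicated(nm) > 0)
  # order: regions block first, in region-major feature-minor order
  expect_identical(nm[1:8], paste0("frontal_left_",
                                   eegresponse:::feature_order))
  expect_identical(nm[113:120], paste0("asym_frontal_",
                                       eegresponse:::feature_order))
})

test_that("feature extraction is invariant to channel order in the file", {
  spec <- quick_spec(seed = 41)
  rec <- generate_subject_eeg(spec, "responder", 1)
  set.seed(99)
  perm <- sample(seq_along(rec$channel_labels))
  shuffled <- recording(rec$samples[perm, ], rec$channel_labels[perm],
                        rec$sfreq, rec$subject_id)
  fv1 <- extract_features(rec, mse = mse_fast())
  fv2 <- extract_features(shuffled, mse = mse_fast())
  expect_equal(fv1, fv2)
})

test_that("feature vectors are invariant to global amplitude rescaling", {
  spec <- quick_spec(seed = 42)
  rec <- generate_subject_eeg(spec, "responder", 2)
  scaled <- recording(rec$samples * 3.7, rec$channel_labels, rec$sfreq,
                      rec$subject_id)
  cfg <- cleaning_config(amplitude_threshold = 1e6)  # keep both fully intact
  fv1 <- extract_features(rec, cleaning = cfg, mse = mse_fast())
  fv2 <- extract_features(scaled, cleaning = cfg, mse = mse_fast())
  expect_equal(fv1, fv2, tolerance = 1e-9)
})

test_that("build_feature_matrix excludes failing subjects and stays deterministic", {
  spec <- quick_spec(seed = 43)
  recs <- list(S001 = generate_subject_eeg(spec, "responder", 1, "S001"),
               S002 = generate_subject_eeg(spec, "nonresponder", 2, "S002"))
  short <- recs$S001
  short$samples <- short$samples[, 1:(20 * short$sfreq)]  # 20 s only
  recs$S003 <- recording(short$samples, short$channel_labels, short$sfreq, "S003")
  fm <- suppressMessages(build_feature_matrix(recs, mse = mse_fast()))
  expect_s3_class(fm, "eeg_feature_matrix")
  expect_equal(dim(fm), c(2L, 153L))
  excl <- attr(fm, "exclusions")
  expect_equal(excl$subject_id, "S003")
  # identical recording submitted twice gives identical rows
  recs2 <- list(A = recs$S001, B = recs$S001)
  fm2 <- build_feature_matrix(recs2, mse = mse_fast())
  expect_equal(as.numeric(fm2[1, -1]), as.numeric(fm2[2, -1]))
  # all excluded -> pipeline error
  expect_error(
    suppressMessages(build_feature_matrix(list(X = recs$S003),
                                          mse = mse_fast())),
    class = "eegresponse_error_pipeline")
})
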