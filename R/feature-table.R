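feature_order <- c("delta", "theta", "alpha", "beta", "gamma",
                   "mse_fine", "mse_medium", "mse_coarse")

pair_basename <- function(pair) {
  base <- sub("_left$", "", pair[1])
  if (identical(base, pair[1])) base <- paste0(pair[1], "_over_", pair[2])
  base
}

#' Frozen feature-vector column names
#'
#' The subject feature vector concatenates, in a fixed and versioned order,
#' the 8 features (5 relative band powers + 3 entropy timescale bands) for
#' each region, followed by the same 8 features for each left/right
#' asymmetry pair. With the default 14-region / 5-pair map this gives
#' 14 x 8 + 5 x 8 = 152 named columns. Freezing the order here guarantees a
#' trained model and an external cohort can never silently misalign.
#'
#' @param map An [region_map()], default [default_region_map()].
#' @return Character vector of feature names.
#' @export
feature_names <- function(map = default_region_map()) {
  c(as.vector(t(outer(map$region_names, feature_order, paste, sep = "_"))),
    as.vector(t(outer(vapply(map$pairs, pair_basename, ""),
                      feature_order, function(p, f)
                        paste0("asym_", p, "_", f)))))
}

#' Average channel features within regions
#'
#' @param channel_features Tibble with a `channel` column and the 8 feature
#'   columns, one row per channel.
#' @param mapping Named list region -> channel indices, from
#'   [validate_montage()].
#' @return Tibble: one row per region, columns `region` + the 8 features.
#' @export
region_average <- function(channel_features, mapping) {
  missing_cols <- setdiff(feature_order, names(channel_features))
  if (length(missing_cols))
    stop_input(paste0("Channel feature table lacks column(s): ",
                      paste(missing_cols, collapse = ", ")), "shape")
  if (any(vapply(mapping, length, 1L) == 0L))
    stop_input("Every region must have at least one channel.", "montage")
  rows <- purrr::imap(mapping, function(idx, region) {
    sub <- channel_features[idx, feature_order]
    dplyr::bind_cols(tibble::tibble(region = region),
                     dplyr::summarise(sub, dplyr::across(
                       dplyr::everything(), mean)))
  })
  dplyr::bind_rows(rows)
}

#' Hemispheric asymmetry features
#'
#' Left-region feature divided by right-region feature for each asymmetry
#' pair. A right-side value of magnitude below `eps` indicates a degenerate
#' signal and fails loudly rather than producing an unbounded ratio.
#'
#' @param region_features Output of [region_average()].
#' @param pairs List of `c(left, right)` region name pairs.
#' @param eps Division guard for near-zero denominators.
#' @return Tibble: one row per pair, columns `pair` + the 8 feature ratios.
#' @export
asymmetry_features <- function(region_features, pairs, eps = 1e-12) {
  rows <- purrr::map(pairs, function(pr) {
    li <- match(pr[1], region_features$region)
    ri <- match(pr[2], region_features$region)
    if (is.na(li) || is.na(ri))
      stop_input(paste0("Pair member missing from region features: ",
                        paste(pr, collapse = "/")), "shape")
    lv <- as.numeric(region_features[li, feature_order])
    rv <- as.numeric(region_features[ri, feature_order])
    bad <- which(abs(rv) < eps)
    if (length(bad))
      stop_input(sprintf(
        "Right-hemisphere value of '%s' is ~0 for pair %s; asymmetry undefined.",
        feature_order[bad[1]], pair_basename(pr)), "division_guard")
    out <- tibble::as_tibble(as.list(stats::setNames(lv / rv, feature_order)))
    dplyr::bind_cols(tibble::tibble(pair = pair_basename(pr)), out)
  })
  dplyr::bind_rows(rows)
}

#' Assemble the subject feature vector
#'
#' Concatenates region features then asymmetry features, each in the frozen
#' region x feature order of [feature_names()].
#'
#' @param region_features Output of [region_average()].
#' @param asymmetries Output of [asymmetry_features()].
#' @param map The [region_map()] defining the expected order.
#' @return Named numeric vector (152 entries for the default map).
#' @export
assemble_features <- function(region_features, asymmetries,
                              map = default_region_map()) {
  if (!identical(region_features$region, map$region_names))
    stop_input("Region features do not match the map's region order.", "shape")
  expected_pairs <- vapply(map$pairs, pair_basename, "")
  if (!identical(asymmetries$pair, expected_pairs))
    stop_input("Asymmetry rows do not match the map's pair order.", "shape")
  vals <- c(as.vector(t(as.matrix(region_features[, feature_order]))),
            as.vector(t(as.matrix(asymmetries[, feature_order]))))
  stats::setNames(vals, feature_names(map))
}

#' Per-channel spectral and entropy features of one recording
#'
#' Runs the full single-subject feature stage: optional cleaning, Welch
#' relative band power per channel over the whole recording, and multiscale
#' entropy per channel averaged over nonoverlapping 30-s windows and then
#' over the three timescale bands.
#'
#' @param rec An `eeg_recording`.
#' @param cleaning [cleaning_config()] or `NULL` to skip cleaning.
#' @param spectral An [spectral_config()].
#' @param mse An [mse_config()].
#' @return Tibble: one row per channel, columns `channel` + the 8 features.
#' @export
channel_features <- function(rec,
                             cleaning = cleaning_config(),
                             spectral = spectral_config(),
                             mse = mse_config()) {
  if (!is.null(cleaning)) rec <- clean_recording(rec, cleaning)
  win <- segment_windows(rec, mse$mse_window)
  curves <- lapply(win$windows, mse_curve, sfreq = rec$sfreq, cfg = mse)
  counts <- Reduce(`+`, lapply(curves, function(m) 1 * !is.na(m)))
  sums <- Reduce(`+`, lapply(curves, function(m) { m[is.na(m)] <- 0; m }))
  mean_curve <- sums / pmax(counts, 1)      # mean over windows, per scale
  mean_curve[counts == 0] <- NA_real_

  rows <- purrr::map(seq_along(rec$channel_labels), function(ch) {
    psd <- welch_psd(rec$samples[ch, ], rec$sfreq, spectral)
    rbp <- relative_band_power(psd, spectral)
    ent <- mse_band_average(mean_curve[ch, ], mse)
    tibble::tibble(channel = rec$channel_labels[ch],
                   !!!stats::setNames(as.list(rbp$relative_power), rbp$band),
                   !!!stats::setNames(as.list(ent$entropy),
                                      paste0("mse_", ent$band)))
  })
  dplyr::bind_rows(rows)
}

#' Extract one subject's assembled feature vector
#'
#' @inheritParams channel_features
#' @param map An [region_map()].
#' @return Named numeric feature vector (see [feature_names()]).
#' @export
extract_features <- function(rec,
                             map = default_region_map(),
                             cleaning = cleaning_config(),
                             spectral = spectral_config(),
                             mse = mse_config()) {
  if (!is.null(cleaning)) {
    rec <- clean_recording(rec, cleaning)
    cleaning <- NULL
  }
  mapping <- validate_montage(rec, map)
  cf <- channel_features(rec, cleaning = NULL, spectral = spectral, mse = mse)
  rf <- region_average(cf, lapply(mapping, function(idx)
    match(rec$channel_labels[idx], cf$channel)))
  af <- asymmetry_features(rf, map$pairs)
  assemble_features(rf, af, map)
}

#' Build the cohort feature matrix
#'
#' Extracts the feature vector for every recording. Subjects whose
#' recordings fail a quality or data-sufficiency check (cleaning retained
#' too little data, recording shorter than one entropy window, degenerate
#' signals) are excluded rather than aborting the cohort; exclusions and
#' their reasons are attached as the `"exclusions"` attribute and reported.
#'
#' @param recordings Named list of `eeg_recording` objects (names =
#'   subject ids), e.g. from [generate_cohort()].
#' @inheritParams extract_features
#' @return A tibble of class `eeg_feature_matrix`: `subject_id` column plus
#'   one column per feature; attribute `exclusions` is a tibble
#'   (`subject_id`, `reason`).
#' @export
build_feature_matrix <- function(recordings,
                                 map = default_region_map(),
                                 cleaning = cleaning_config(),
                                 spectral = spectral_config(),
                                 mse = mse_config()) {
  ids <- names(recordings) %||%
    vapply(recordings, function(r) r$subject_id, "")
  rows <- list(); excl <- list()
  for (i in seq_along(recordings)) {
    fv <- tryCatch(
      extract_features(recordings[[i]], map, cleaning, spectral, mse),
      eegresponse_error = function(e) e)
    if (inherits(fv, "error")) {
      excl[[length(excl) + 1L]] <-
        tibble::tibble(subject_id = ids[i], reason = conditionMessage(fv))
    } else {
      rows[[length(rows) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(subject_id = ids[i]),
                         tibble::as_tibble(as.list(fv)))
    }
  }
  if (!length(rows))
    stop_input("No subject survived feature extraction.", "pipeline")
  excl_tbl <- if (length(excl)) dplyr::bind_rows(excl) else
    tibble::tibble(subject_id = character(), reason = character())
  if (nrow(excl_tbl))
    inform(paste0("Excluded ", nrow(excl_tbl), " subject(s): ",
                  paste(excl_tbl$subject_id, collapse = ", ")))
  out <- dplyr::bind_rows(rows)
  attr(out, "exclusions") <- excl_tbl
  class(out) <- c("eeg_feature_matrix", class(out))
  out
}

#' Convert a feature matrix tibble to a plain numeric matrix
#'
#' @param x An `eeg_feature_matrix` (or any tibble with `subject_id` plus
#'   numeric feature columns).
#' @return Numeric matrix with subject ids as row names.
#' @export
feature_matrix_values <- function(x) {
  m <- as.matrix(x[, setdiff(names(x), "subject_id")])
  rownames(m) <- x$subject_id
  m
}
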