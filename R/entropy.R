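#' Multiscale entropy configuration
#'
#' Settings for multiscale sample entropy: embedding dimension `m`,
#' similarity tolerance `r` expressed as a fraction of the signal's standard
#' deviation, the coarse-graining scales, the analysis window length, and
#' the three timescale bands over which the entropy curve is averaged
#' (fine 1-20, medium 21-35, coarse 36-70 by default).
#'
#' @param m Embedding dimension (template length), default 2.
#' @param r Similarity tolerance as a fraction of SD, default 0.15.
#' @param scales Integer vector of coarse-graining scales, contiguous from 1.
#' @param mse_window Entropy analysis window length in seconds, default 30.
#' @param timescale_bands Named list of length-2 integer ranges partitioning
#'   `scales`.
#' @param r_per_scale If `TRUE`, re-estimate the tolerance from the SD of
#'   each coarse-grained series instead of holding the scale-1 tolerance
#'   fixed across scales (the default convention).
#' @return An object of class `eeg_mse_config`.
#' @export
mse_config <- function(m = 2, r = 0.15, scales = 1:70, mse_window = 30,
                       timescale_bands = list(fine = c(1, 20),
                                              medium = c(21, 35),
                                              coarse = c(36, 70)),
                       r_per_scale = FALSE) {
  if (m < 1) stop_input("`m` must be >= 1.", "parameter")
  if (r <= 0) stop_input("`r` must be > 0.", "parameter")
  scales <- as.integer(scales)
  if (scales[1] != 1L || any(diff(scales) != 1L))
    stop_input("`scales` must be contiguous integers starting at 1.", "parameter")
  covered <- as.integer(unlist(lapply(timescale_bands, function(b)
    seq(b[1], b[2]))))
  if (!identical(sort(covered), sort(scales)))
    stop_input("`timescale_bands` must partition `scales`.", "parameter")
  structure(list(m = as.integer(m), r = r, scales = scales,
                 mse_window = mse_window, timescale_bands = timescale_bands,
                 r_per_scale = isTRUE(r_per_scale)),
            class = "eeg_mse_config")
}

#' Coarse-grain a series
#'
#' Replaces a series by the means of consecutive nonoverlapping blocks of
#' length `scale`; the output has `floor(length(x) / scale)` points. Scale 1
#' is the identity.
#'
#' @param x Numeric vector.
#' @param scale Positive integer block length.
#' @return Numeric vector of block means.
#' @export
coarse_grain <- function(x, scale) {
  scale <- as.integer(scale)
  if (is.na(scale) || scale < 1L)
    stop_input("`scale` must be a positive integer.", "parameter")
  if (scale == 1L) return(as.numeric(x))
  n <- length(x) %/% scale
  if (n < 1L)
    stop_input("Series shorter than one coarse-graining block.", "parameter")
  colMeans(matrix(x[seq_len(n * scale)], nrow = scale))
}

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A / B), where B counts pairs of length-`m` templates
#' within Chebyshev distance `r_abs` of each other (self-matches excluded)
#' and A counts the same for length `m + 1`. Templates are taken at offsets
#' `1 .. N - m` so both counts run over the same template set and a constant
#' series gives exactly 0.
#'
#' Degenerate counts are handled deterministically: if `B = 0` (no matches
#' at length `m`) the entropy is undefined and `NA` is returned; if `A = 0`
#' with `B > 0` the value is capped at `log(B + 1)`, a finite stand-in for
#' an unobservably large entropy.
#'
#' @param x Numeric vector.
#' @param m Embedding dimension.
#' @param r_abs Absolute similarity tolerance (same units as `x`).
#' @return Entropy value (unitless), `NA` if undefined.
#' @export
sample_entropy <- function(x, m = 2, r_abs) {
  if (r_abs <= 0) stop_input("`r_abs` must be > 0.", "parameter")
  m <- as.integer(m)
  if (length(x) <= m + 1L)
    stop_input("Series must be longer than m + 1.", "insufficient_data")
  cnt <- sampen_counts_cpp(as.numeric(x), m, r_abs)
  a <- cnt[1]; b <- cnt[2]
  if (b == 0) return(NA_real_)
  if (a == 0) return(log(b + 1))
  -log(a / b)
}

#' Multiscale entropy curve of a windowed multichannel signal
#'
#' Computes sample entropy of every channel at each coarse-graining scale.
#' The tolerance is `r x SD` of the channel within this window at scale 1
#' and is held fixed across scales (set `r_per_scale = TRUE` in the config
#' to re-estimate it per scale instead).
#'
#' @param window Numeric matrix, channels x time (one analysis window).
#' @param sfreq Sampling frequency in Hz (retained for validation).
#' @param cfg An [mse_config()].
#' @return Numeric matrix, channels x scales, of entropy values (may contain
#'   `NA` where undefined).
#' @export
mse_curve <- function(window, sfreq, cfg = mse_config()) {
  stopifnot(inherits(cfg, "eeg_mse_config"))
  window <- as.matrix(window)
  out <- matrix(NA_real_, nrow(window), length(cfg$scales),
                dimnames = list(rownames(window), cfg$scales))
  n_min <- ncol(window) %/% max(cfg$scales)
  if (n_min <= cfg$m + 1L)
    stop_input(sprintf(
      "Coarse-grained series at scale %d has %d points; need > m + 1.",
      max(cfg$scales), n_min), "scale_length")
  for (ch in seq_len(nrow(window))) {
    x <- window[ch, ]
    r_abs <- cfg$r * sd(x)
    if (!is.finite(r_abs) || r_abs <= 0) next  # flat channel: undefined
    if (!cfg$r_per_scale) {
      # all scales in one compiled pass with the scale-1 tolerance
      cnt <- mse_counts_cpp(as.numeric(x), cfg$m, r_abs, length(cfg$scales))
      out[ch, ] <- ifelse(cnt[2, ] == 0, NA_real_,
                          ifelse(cnt[1, ] == 0, log(cnt[2, ] + 1),
                                 -log(cnt[1, ] / cnt[2, ])))
    } else {
      for (si in seq_along(cfg$scales)) {
        xc <- coarse_grain(x, cfg$scales[si])
        out[ch, si] <- sample_entropy(xc, cfg$m, cfg$r * sd(xc))
      }
    }
  }
  out
}

#' Average an entropy curve within timescale bands
#'
#' Arithmetic mean of the entropy curve within each configured timescale
#' band. Undefined scales (`NA`) are excluded from the mean; a band with no
#' defined scale at all is an error since the corresponding feature would be
#' meaningless.
#'
#' @param curve Numeric vector of entropy values, one per scale.
#' @param cfg An [mse_config()].
#' @return A tibble with columns `band` and `entropy`.
#' @export
mse_band_average <- function(curve, cfg = mse_config()) {
  stopifnot(inherits(cfg, "eeg_mse_config"))
  if (length(curve) != length(cfg$scales))
    stop_input(sprintf("Curve has %d values but %d scales are configured.",
                       length(curve), length(cfg$scales)), "shape")
  vals <- vapply(names(cfg$timescale_bands), function(bn) {
    b <- cfg$timescale_bands[[bn]]
    v <- curve[cfg$scales >= b[1] & cfg$scales <= b[2]]
    if (all(is.na(v)))
      stop_input(paste0("All scales undefined in timescale band ", bn, "."),
                 "feature_quality")
    mean(v, na.rm = TRUE)
  }, 1)
  tibble::tibble(band = names(cfg$timescale_bands), entropy = unname(vals))
}
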