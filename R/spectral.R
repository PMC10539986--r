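#' Spectral feature configuration
#'
#' Settings for Welch power spectral density estimation and relative band
#' power. Defaults follow common clinical practice: 2-second nonoverlapping
#' Hamming-tapered segments, an analysis range of 1-50 Hz, and the five
#' canonical bands delta (1-4 Hz), theta (4-8), alpha (8-13), beta (13-30)
#' and gamma (30-50). Bands are half-open `[low, high)` except the last,
#' which is closed at the upper analysis edge, so together they tile the
#' analysis range exactly.
#'
#' @param welch_window Welch segment length in seconds.
#' @param overlap Fractional overlap between Welch segments in `[0, 1)`.
#' @param freq_range Length-2 numeric, analysis range in Hz.
#' @param bands Named list of length-2 numeric band edges in Hz.
#' @return An object of class `eeg_spectral_config`.
#' @export
spectral_config <- function(welch_window = 2,
                            overlap = 0,
                            freq_range = c(1, 50),
                            bands = list(delta = c(1, 4), theta = c(4, 8),
                                         alpha = c(8, 13), beta = c(13, 30),
                                         gamma = c(30, 50))) {
  if (overlap < 0 || overlap >= 1)
    stop_input("`overlap` must be in [0, 1).", "parameter")
  if (freq_range[1] >= freq_range[2] || freq_range[1] <= 0)
    stop_input("`freq_range` must be (low, high) with 0 < low < high.", "parameter")
  edges <- do.call(rbind, bands)
  ord <- order(edges[, 1])
  edges <- edges[ord, , drop = FALSE]
  if (any(edges[, 1] >= edges[, 2]))
    stop_input("Each band must have low < high.", "parameter")
  contiguous <- all(abs(edges[-1, 1] - edges[-nrow(edges), 2]) < 1e-9)
  covers <- abs(edges[1, 1] - freq_range[1]) < 1e-9 &&
    abs(edges[nrow(edges), 2] - freq_range[2]) < 1e-9
  if (!contiguous || !covers)
    stop_input("Bands must be disjoint, contiguous and jointly cover `freq_range`.",
               "parameter")
  structure(list(welch_window = welch_window, overlap = overlap,
                 freq_range = as.numeric(freq_range),
                 bands = bands[names(bands)[ord]]),
            class = "eeg_spectral_config")
}

#' Welch power spectral density
#'
#' Averages one-sided modified periodograms over Hamming-tapered segments of
#' `welch_window` seconds (nonoverlapping by default). Frequency resolution
#' is `1 / welch_window` Hz. Power is returned as a density in uV^2/Hz over
#' the configured analysis range.
#'
#' @param x Numeric vector, one channel's samples in uV.
#' @param sfreq Sampling frequency in Hz.
#' @param cfg An [spectral_config()].
#' @param restrict If `TRUE` (default) keep only frequencies inside
#'   `cfg$freq_range`.
#' @return A tibble with columns `frequency` (Hz) and `power` (uV^2/Hz).
#' @export
welch_psd <- function(x, sfreq, cfg = spectral_config(), restrict = TRUE) {
  stopifnot(inherits(cfg, "eeg_spectral_config"))
  seg <- as.integer(round(cfg$welch_window * sfreq))
  if (length(x) < seg)
    stop_input(sprintf(
      "Signal of %d samples is shorter than one %g-s Welch segment (%d samples).",
      length(x), cfg$welch_window, seg), "insufficient_data")
  step <- max(1L, as.integer(round(seg * (1 - cfg$overlap))))
  starts <- seq(1L, length(x) - seg + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(seg - 1)) / (seg - 1))  # Hamming
  scale <- 1 / (sfreq * sum(w^2))
  n_freq <- seg %/% 2 + 1L
  acc <- numeric(n_freq)
  for (s in starts) {
    segment <- x[s:(s + seg - 1L)]
    segment <- (segment - mean(segment)) * w
    p <- abs(fft(segment)[seq_len(n_freq)])^2 * scale
    # one-sided density: double everything except DC (and Nyquist if present)
    p[2:(n_freq - 1L)] <- 2 * p[2:(n_freq - 1L)]
    if (seg %% 2 == 1L) p[n_freq] <- 2 * p[n_freq]
    acc <- acc + p
  }
  freqs <- (seq_len(n_freq) - 1L) * sfreq / seg
  out <- tibble::tibble(frequency = freqs, power = acc / length(starts))
  if (restrict)
    out <- out[out$frequency >= cfg$freq_range[1] &
                 out$frequency <= cfg$freq_range[2], ]
  out
}

#' Relative band power
#'
#' Integrates spectral power within each configured band and divides by the
#' total power over the analysis range, so the five values sum to one.
#' Bands are half-open `[low, high)` except the last, closed at the upper
#' analysis edge.
#'
#' @param psd A tibble with `frequency` and `power` columns (e.g. from
#'   [welch_psd()]).
#' @param cfg An [spectral_config()].
#' @return A tibble with columns `band` and `relative_power`.
#' @export
relative_band_power <- function(psd, cfg = spectral_config()) {
  stopifnot(inherits(cfg, "eeg_spectral_config"))
  f <- psd$frequency; p <- psd$power
  in_range <- f >= cfg$freq_range[1] & f <= cfg$freq_range[2]
  f <- f[in_range]; p <- p[in_range]
  total <- sum(p)
  if (!is.finite(total) || total <= 0)
    stop_input("Total spectral power over the analysis range is zero.",
               "degenerate_signal")
  bn <- names(cfg$bands)
  vals <- vapply(seq_along(cfg$bands), function(i) {
    b <- cfg$bands[[i]]
    mask <- if (i == length(cfg$bands)) f >= b[1] & f <= b[2] else f >= b[1] & f < b[2]
    sum(p[mask]) / total
  }, 1)
  tibble::tibble(band = bn, relative_power = vals)
}
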