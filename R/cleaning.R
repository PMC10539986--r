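#' Cleaning-stage configuration
#'
#' Parameterizes the automated artifact-rejection stage: a zero-phase
#' band-pass filter followed by peak-to-peak rejection of fixed-length
#' segments. This stage is deliberately simple and fully deterministic so it
#' can run unattended; it is isolated behind this one configuration object
#' so a site-specific cleaning pipeline can be swapped in.
#'
#' @param bandpass Length-2 numeric, `(low, high)` cut-offs in Hz.
#' @param amplitude_threshold Peak-to-peak rejection threshold in uV; any
#'   2-second segment in which any channel spans more than this is dropped.
#' @param min_retained_fraction Minimum fraction of segments that must
#'   survive rejection; below this the recording fails with a quality error.
#' @param segment_length Rejection segment length in seconds.
#' @return An object of class `eeg_cleaning_config`.
#' @export
cleaning_config <- function(bandpass = c(1, 50),
                            amplitude_threshold = 150,
                            min_retained_fraction = 0.5,
                            segment_length = 2) {
  if (length(bandpass) != 2L || bandpass[1] >= bandpass[2])
    stop_input("`bandpass` must be (low, high) with low < high.", "parameter")
  if (amplitude_threshold <= 0)
    stop_input("`amplitude_threshold` must be positive.", "parameter")
  if (min_retained_fraction <= 0 || min_retained_fraction > 1)
    stop_input("`min_retained_fraction` must be in (0, 1].", "parameter")
  structure(list(bandpass = as.numeric(bandpass),
                 amplitude_threshold = amplitude_threshold,
                 min_retained_fraction = min_retained_fraction,
                 segment_length = segment_length),
            class = "eeg_cleaning_config")
}

# zero-phase 4th-order Butterworth band-pass, applied per channel
bandpass_filter <- function(samples, sfreq, band) {
  nyq <- sfreq / 2
  if (band[2] >= nyq)
    stop_input("Band-pass upper edge must be below the Nyquist frequency.",
               "parameter")
  bf <- signal::butter(4, band / nyq, type = "pass")
  t(apply(samples, 1, function(ch) signal::filtfilt(bf, ch)))
}

#' Clean a recording
#'
#' Applies a zero-phase Butterworth band-pass, splits the recording into
#' fixed-length segments, drops every segment in which any channel exceeds
#' the peak-to-peak amplitude threshold, and re-concatenates the survivors.
#' Deterministic: the same input and configuration always give the same
#' output, and a second pass is a no-op (nothing exceeds the threshold after
#' the first).
#'
#' @param rec An `eeg_recording`.
#' @param cfg An [cleaning_config()].
#' @return A cleaned `eeg_recording` (possibly shorter than the input).
#' @export
clean_recording <- function(rec, cfg = cleaning_config()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(cfg, "eeg_cleaning_config"))
  filtered <- bandpass_filter(rec$samples, rec$sfreq, cfg$bandpass)
  seg_len <- as.integer(round(cfg$segment_length * rec$sfreq))
  n <- ncol(filtered)
  n_seg <- ceiling(n / seg_len)      # trailing partial segment checked too
  keep <- logical(n_seg)
  for (s in seq_len(n_seg)) {
    cols <- (((s - 1) * seg_len + 1):min(s * seg_len, n))
    p2p <- apply(filtered[, cols, drop = FALSE], 1, function(ch)
      max(ch) - min(ch))
    keep[s] <- all(p2p <= cfg$amplitude_threshold)
  }
  retained <- mean(keep)
  if (retained < cfg$min_retained_fraction)
    stop_input(sprintf(
      "Only %.1f%% of segments survive amplitude rejection for subject %s (minimum %.1f%%).",
      100 * retained, rec$subject_id, 100 * cfg$min_retained_fraction),
      "quality", retained_fraction = retained, subject_id = rec$subject_id)
  cols_keep <- unlist(lapply(which(keep), function(s)
    ((s - 1) * seg_len + 1):min(s * seg_len, n)))
  recording(filtered[, cols_keep, drop = FALSE], rec$channel_labels,
            rec$sfreq, rec$subject_id)
}

#' Split a recording into nonoverlapping windows
#'
#' Cuts the recording into `floor(duration / window_length)` contiguous,
#' nonoverlapping windows, discarding any trailing remainder. Spectral
#' features use 2-second windows (inside the Welch estimator); multiscale
#' entropy uses 30-second windows.
#'
#' @param rec An `eeg_recording`.
#' @param window_length Window length in seconds.
#' @return An object of class `eeg_windows`: list with `subject_id`,
#'   `window_length`, `sfreq` and `windows` (list of channels x time
#'   matrices).
#' @export
segment_windows <- function(rec, window_length) {
  stopifnot(inherits(rec, "eeg_recording"))
  wl <- as.integer(round(window_length * rec$sfreq))
  n <- ncol(rec$samples)
  n_win <- n %/% wl
  if (n_win < 1)
    stop_input(sprintf(
      "Recording %s is %.1f s long; at least %g s needed for one window.",
      rec$subject_id, n / rec$sfreq, window_length),
      "insufficient_data", subject_id = rec$subject_id)
  windows <- lapply(seq_len(n_win), function(w)
    rec$samples[, ((w - 1) * wl + 1):(w * wl), drop = FALSE])
  structure(list(subject_id = rec$subject_id,
                 window_length = window_length,
                 sfreq = rec$sfreq,
                 windows = windows),
            class = "eeg_windows")
}

#' @export
print.eeg_windows <- function(x, ...) {
  cat(sprintf("<eeg_windows> subject %s: %d windows of %g s\n",
              x$subject_id, length(x$windows), x$window_length))
  invisible(x)
}
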