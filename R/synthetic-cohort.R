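#' Specification of a synthetic EEG cohort
#'
#' Describes a cohort of simulated resting-state, eyes-closed EEG subjects
#' with matching clinical score tables. Each channel is a mixture of a
#' `1/f^beta` background, band-limited oscillations (band-pass-filtered
#' noise, so narrow-band power fluctuates naturally across time), and a
#' broadband white component. Two class-conditional effects are available:
#'
#' * `asymmetry_effect`: left-hemisphere alpha-band oscillation amplitude is
#'   multiplied by `1 + asymmetry_effect` for responders only, creating an
#'   interhemispheric alpha-power contrast between classes.
#' * `complexity_effect`: the broadband mixing fraction is multiplied by
#'   `1 + complexity_effect` for responders only, shifting signal
#'   irregularity (and hence fine-scale entropy) between classes.
#'
#' With both effects at 0 the two classes are exchangeable in distribution.
#'
#' @param n_responders,n_nonresponders Subject counts per class (sum >= 2).
#' @param sfreq Sampling rate in Hz (>= 128).
#' @param duration Recording length in seconds (>= 60, i.e. at least two
#'   30-s entropy windows).
#' @param channel_labels Montage labels; default the standard 32-channel set.
#' @param background_exponent Spectral exponent beta of the `1/f^beta`
#'   background.
#' @param oscillations List of length-3 numeric vectors
#'   `c(center_hz, bandwidth_hz, relative_amplitude)`.
#' @param asymmetry_effect,complexity_effect Unitless class contrasts, see
#'   above.
#' @param noise_fraction Baseline broadband mixing fraction in `[0, 0.95]`.
#' @param amplitude_uv Overall per-channel signal SD in uV.
#' @param scale_baseline Length-2 numeric `c(mean, sd)` of the MADRS-like
#'   baseline severity score.
#' @param seed Master seed; all cohort randomness derives from it.
#' @return An object of class `eeg_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_responders,
                                  n_nonresponders,
                                  sfreq = 250,
                                  duration = 120,
                                  channel_labels = default_channel_labels(),
                                  background_exponent = 1,
                                  oscillations = list(alpha = c(10, 4, 1),
                                                      beta = c(20, 6, 0.25)),
                                  asymmetry_effect = 0,
                                  complexity_effect = 0,
                                  noise_fraction = 0.3,
                                  amplitude_uv = 10,
                                  scale_baseline = c(mean = 30, sd = 5.8),
                                  seed = 1) {
  if (n_responders < 0 || n_nonresponders < 0 ||
      n_responders + n_nonresponders < 2)
    stop_input("Need n_responders >= 0, n_nonresponders >= 0 and at least 2 subjects.",
               "cohort_spec")
  if (sfreq < 128)
    stop_input("`sfreq` must be >= 128 Hz to support the 1-50 Hz analysis range.",
               "cohort_spec")
  if (duration < 60)
    stop_input("`duration` must be >= 60 s (two 30-s entropy windows).",
               "cohort_spec")
  n_samples <- duration * sfreq * length(channel_labels)
  if (n_samples > 2^31 - 1)
    stop_input("duration x sfreq x channels overflows a sane sample budget.",
               "cohort_spec")
  if (noise_fraction < 0 || noise_fraction > 0.95)
    stop_input("`noise_fraction` must be in [0, 0.95].", "cohort_spec")
  structure(
    list(n_responders = as.integer(n_responders),
         n_nonresponders = as.integer(n_nonresponders),
         sfreq = sfreq, duration = duration,
         channel_labels = canonical_label(channel_labels),
         background_exponent = background_exponent,
         oscillations = oscillations,
         asymmetry_effect = asymmetry_effect,
         complexity_effect = complexity_effect,
         noise_fraction = noise_fraction,
         amplitude_uv = amplitude_uv,
         scale_baseline = scale_baseline,
         seed = as.integer(seed)),
    class = "eeg_cohort_spec")
}

# 1/f^beta Gaussian background via spectral shaping of white noise, unit SD
one_over_f_noise <- function(n, sfreq, beta) {
  z <- fft(rnorm(n))
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * sfreq / n    # |frequency| of each FFT bin
  gain <- ifelse(f > 0, f^(-beta / 2), 0)
  x <- Re(fft(z * gain, inverse = TRUE)) / n
  x / sd(x)
}

# band-limited oscillation: band-pass-filtered white noise, unit SD
narrowband_noise <- function(n, sfreq, center, bandwidth) {
  lo <- max(center - bandwidth / 2, 0.1)
  hi <- min(center + bandwidth / 2, sfreq / 2 * 0.99)
  bf <- signal::butter(4, c(lo, hi) / (sfreq / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  x / sd(x)
}

#' Generate one subject's synthetic EEG
#'
#' Deterministic given `(spec$seed, subject_seed, class_label)`; channels
#' are mutually independent realizations of the same generative model.
#'
#' @param spec An [synthetic_cohort_spec()].
#' @param class_label `"responder"` or `"nonresponder"`.
#' @param subject_seed Integer subject stream index.
#' @param subject_id Identifier for the returned recording.
#' @return An `eeg_recording`.
#' @export
generate_subject_eeg <- function(spec, class_label, subject_seed,
                                 subject_id = paste0("S", subject_seed)) {
  stopifnot(inherits(spec, "eeg_cohort_spec"))
  if (!class_label %in% c("responder", "nonresponder"))
    stop_input(paste0("Unknown class label: ", class_label), "class_label")
  is_resp <- class_label == "responder"
  n <- as.integer(round(spec$duration * spec$sfreq))
  hemis <- hemisphere_of(spec$channel_labels)
  w <- spec$noise_fraction * (if (is_resp) 1 + spec$complexity_effect else 1)
  w <- min(max(w, 0), 0.95)

  with_local_seed(
    derive_seed(spec$seed, subject_seed, as.integer(is_resp)), {
      samples <- matrix(0, length(spec$channel_labels), n)
      for (ch in seq_along(spec$channel_labels)) {
        structured <- one_over_f_noise(n, spec$sfreq, spec$background_exponent)
        for (osc in spec$oscillations) {
          amp <- osc[3]
          alpha_band <- osc[1] >= 8 && osc[1] <= 13
          if (alpha_band && is_resp && hemis[ch] == "left")
            amp <- amp * (1 + spec$asymmetry_effect)
          structured <- structured +
            amp * narrowband_noise(n, spec$sfreq, osc[1], osc[2])
        }
        structured <- structured / sd(structured)
        x <- (1 - w) * structured + w * rnorm(n)
        samples[ch, ] <- spec$amplitude_uv * x / sd(x)
      }
      recording(samples, spec$channel_labels, spec$sfreq, subject_id)
    })
}

#' Generate a full synthetic cohort
#'
#' Produces one recording per subject plus a clinical score table. Baseline
#' scores are drawn from the configured severity distribution (integer,
#' floored at 10); week-8 scores are constructed so that the standard
#' response rule -- a reduction of 50% or more from baseline -- recovers the
#' generating class exactly: responders draw a reduction uniform in
#' `[55%, 85%]`, nonresponders in `[0%, 45%]`, with rounding directions that
#' cannot cross the 50% threshold.
#'
#' @param spec An [synthetic_cohort_spec()].
#' @param id_prefix Prefix for generated subject ids (ids are
#'   `<prefix>001`, `<prefix>002`, ...). Give distinct prefixes to cohorts
#'   that will be compared so their ids cannot collide.
#' @return A list with `recordings` (named list of `eeg_recording`) and
#'   `cohort` (tibble: `subject_id`, `group`, `score_week0`, `score_week8`).
#' @export
generate_cohort <- function(spec, id_prefix = "S") {
  stopifnot(inherits(spec, "eeg_cohort_spec"))
  n_total <- spec$n_responders + spec$n_nonresponders
  groups <- rep(c("responder", "nonresponder"),
                c(spec$n_responders, spec$n_nonresponders))
  ids <- sprintf("%s%03d", id_prefix, seq_len(n_total))

  recordings <- lapply(seq_len(n_total), function(i)
    generate_subject_eeg(spec, groups[i], subject_seed = i, subject_id = ids[i]))
  names(recordings) <- ids

  scores <- with_local_seed(derive_seed(spec$seed, 0L, 999L), {
    w0 <- pmax(10L, as.integer(round(rnorm(
      n_total, spec$scale_baseline[["mean"]], spec$scale_baseline[["sd"]]))))
    red <- ifelse(groups == "responder",
                  runif(n_total, 0.55, 0.85),
                  runif(n_total, 0.00, 0.45))
    # floor for responders / ceiling for nonresponders keeps the achieved
    # reduction on the correct side of the 50% rule after integer rounding
    w8 <- ifelse(groups == "responder",
                 floor(w0 * (1 - red)), pmin(w0, ceiling(w0 * (1 - red))))
    tibble::tibble(subject_id = ids, group = groups,
                   score_week0 = as.integer(w0), score_week8 = as.integer(w8))
  })
  list(recordings = recordings, cohort = scores)
}

#' Write a synthetic cohort to disk
#'
#' Saves one recording file per subject (delimited matrix + JSON sidecar, or
#' EDF) and the cohort table as `cohort.csv` with columns `subject_id`,
#' `group`, `score_week0`, `score_week8`.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param format Recording format, `"matrix"` or `"edf"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("matrix", "edf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "edf") ".edf" else ".csv"
  for (id in names(cohort$recordings))
    write_recording(cohort$recordings[[id]],
                    file.path(dir, paste0(id, ext)), format = format)
  utils::write.csv(cohort$cohort, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  invisible(dir)
}
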