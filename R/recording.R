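#' Construct a multichannel EEG recording
#'
#' The in-memory container for one subject's resting-state EEG: an ordered
#' set of channel labels, a sampling rate, and a channels x time sample
#' matrix in microvolts.
#'
#' @param samples Numeric matrix, channels x time, in uV.
#' @param channel_labels Character vector, one label per row of `samples`.
#'   Labels are canonicalized to upper case.
#' @param sfreq Sampling frequency in Hz.
#' @param subject_id Subject identifier string.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(samples, channel_labels, sfreq, subject_id = "unknown") {
  samples <- as.matrix(samples)
  channel_labels <- canonical_label(channel_labels)
  if (nrow(samples) != length(channel_labels))
    stop_input(sprintf(
      "Sample matrix has %d rows but %d channel labels were given.",
      nrow(samples), length(channel_labels)), "metadata")
  if (anyDuplicated(channel_labels))
    stop_input("Duplicate channel labels are not allowed.", "metadata")
  if (!is.numeric(sfreq) || length(sfreq) != 1L || sfreq <= 0)
    stop_input("`sfreq` must be a single positive number (Hz).", "metadata")
  if (!all(is.finite(samples)))
    stop_input("All sample values must be finite.", "metadata")
  rownames(samples) <- channel_labels
  structure(
    list(subject_id = as.character(subject_id),
         channel_labels = channel_labels,
         sfreq = as.numeric(sfreq),
         samples = samples),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$samples), ncol(x$samples), x$sfreq,
              ncol(x$samples) / x$sfreq))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An `eeg_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$sfreq

#' Read a recording from disk
#'
#' Two on-disk formats are supported: `"matrix"`, a delimited channels x
#' samples table (CSV/TSV, no header) with a JSON sidecar
#' `<path>.json` holding `{labels, sfreq_hz, units, subject_id}`; and
#' `"edf"`, 16-bit European Data Format. Labels are canonicalized to upper
#' case and samples converted to uV (EDF physical dimensions "mV" and "V"
#' are rescaled).
#'
#' @param path File path.
#' @param format `"matrix"` or `"edf"`. Default guesses from the extension.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = c("auto", "matrix", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  if (!file.exists(path))
    stop_input(paste0("File not found: ", path), "format")
  switch(format,
         matrix = read_recording_matrix(path),
         edf = read_edf(path))
}

#' Write a recording to disk
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @param format `"matrix"` (delimited + JSON sidecar) or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("matrix", "edf")) {
  format <- match.arg(format)
  switch(format,
         matrix = write_recording_matrix(rec, path),
         edf = write_edf(rec, path))
  invisible(path)
}

read_recording_matrix <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop_input(paste0("Missing JSON sidecar for matrix recording: ", sidecar),
               "metadata")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$sfreq_hz))
    stop_input(paste0("Sidecar lacks `sfreq_hz`: ", sidecar), "metadata")
  mat <- tryCatch(
    as.matrix(utils::read.table(path, sep = ",", header = FALSE)),
    error = function(e) stop_input(
      paste0("Could not parse delimited matrix file: ", path), "format",
      parent = e))
  labels <- meta$labels
  if (length(labels) != nrow(mat))
    stop_input(sprintf(
      "Sidecar lists %d labels but matrix file %s has %d rows.",
      length(labels), path, nrow(mat)), "metadata")
  scale <- unit_scale_to_uv(meta$units %||% "uV")
  recording(mat * scale, labels, meta$sfreq_hz,
            subject_id = meta$subject_id %||% basename(path))
}

write_recording_matrix <- function(rec, path) {
  utils::write.table(
    format(rec$samples, digits = 10, trim = TRUE, scientific = TRUE),
    path, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(labels = rec$channel_labels, sfreq_hz = rec$sfreq,
         units = "uV", subject_id = rec$subject_id),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

unit_scale_to_uv <- function(units) {
  switch(tolower(trimws(units)),
         "uv" = 1, "µv" = 1, "microvolt" = 1,
         "mv" = 1e3, "millivolt" = 1e3,
         "v" = 1e6, "volt" = 1e6,
         stop_input(paste0("Unsupported physical unit: ", units), "metadata"))
}

# --- minimal 16-bit EDF writer/reader -------------------------------------
# EDF stores samples as little-endian int16 with a per-signal linear map
# between digital and physical ranges, in fixed-width ASCII-headed records.
# One-second data records are used, so the sampling rate must be an integer;
# a trailing partial second is dropped on write.

edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  sf <- rec$sfreq
  if (abs(sf - round(sf)) > 1e-9)
    stop_input("EDF export requires an integer sampling rate.", "metadata")
  sf <- as.integer(round(sf))
  ns <- nrow(rec$samples)
  n_rec <- ncol(rec$samples) %/% sf
  if (n_rec < 1)
    stop_input("Recording shorter than one EDF data record (1 s).", "metadata")
  x <- rec$samples[, seq_len(n_rec * sf), drop = FALSE]
  pmin_ <- apply(x, 1, min); pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb"); on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(
    edf_field("0", 8),
    edf_field(rec$subject_id, 80),
    edf_field("eegresponse synthetic/export", 80),
    edf_field("01.01.20", 8), edf_field("00.00.00", 8),
    edf_field(hdr_bytes, 8), edf_field("", 44),
    edf_field(n_rec, 8), edf_field("1", 8), edf_field(ns, 4),
    paste(vapply(rec$channel_labels, edf_field, "", width = 16), collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(rep(edf_field("uV", 8), ns), collapse = ""),
    paste(vapply(sprintf("%.6g", pmin_), edf_field, "", width = 8), collapse = ""),
    paste(vapply(sprintf("%.6g", pmax_), edf_field, "", width = 8), collapse = ""),
    paste(rep(edf_field(dmin, 8), ns), collapse = ""),
    paste(rep(edf_field(dmax, 8), ns), collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(rep(edf_field(sf, 8), ns), collapse = ""),
    paste(rep(edf_field("", 32), ns), collapse = "")
  ), con, eos = NULL)

  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    seg <- x[, ((r - 1) * sf + 1):(r * sf), drop = FALSE]
    dig <- round((seg - pmin_) / gain) + dmin
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  num <- function(s) suppressWarnings(as.numeric(trimws(s)))
  rd(8)                       # version
  subject_id <- trimws(rd(80))
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- num(rd(8))
  rec_dur <- num(rd(8))
  ns <- as.integer(num(rd(4)))
  if (is.na(ns) || ns < 1)
    stop_input(paste0("Unparseable EDF header in ", path), "format")
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  units <- trimws(vapply(seq_len(ns), function(i) rd(8), ""))
  pmin_ <- vapply(seq_len(ns), function(i) num(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) num(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) num(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) num(rd(8)), 0)
  vapply(seq_len(ns), function(i) rd(80), "")
  spr <- vapply(seq_len(ns), function(i) num(rd(8)), 0)
  vapply(seq_len(ns), function(i) rd(32), "")
  if (length(unique(spr)) != 1L)
    stop_input("EDF files with per-signal sampling rates are not supported.",
               "format")
  if (any(is.na(spr)) || spr[1] <= 0 || is.na(rec_dur) || rec_dur <= 0)
    stop_input(paste0("Missing sampling rate in EDF header: ", path), "metadata")
  sf <- spr[1]                 # samples per record; Hz = spr / record duration
  out <- matrix(0, ns, n_rec * sf)
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * sf, size = 2, endian = "little")
    if (length(raw) < ns * sf)
      stop_input(paste0("Truncated EDF data record in ", path), "format")
    block <- matrix(raw, nrow = sf)   # column per signal
    out[, ((r - 1) * sf + 1):(r * sf)] <-
      t(block) * gain + (pmin_ - dmin * gain)
  }
  scale <- vapply(units, function(u)
    if (nzchar(u)) unit_scale_to_uv(u) else 1, 1)
  recording(out * scale, labels, sf / rec_dur, subject_id = subject_id)
}
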