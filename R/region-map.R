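#' Construct a region map
#'
#' A region map assigns each scalp electrode to one of 14 brain regions (5
#' left/right lateral pairs plus 4 midline zones) and names the 5 lateral
#' pairs used for hemispheric-asymmetry features. With 8 features per region
#' this yields the 14 x 8 + 5 x 8 = 152-dimensional subject feature vector.
#'
#' @param regions Named list: region name -> character vector of channel
#'   labels belonging to it.
#' @param pairs List of length-2 character vectors `c(left, right)` naming
#'   the lateral region pairs, left first.
#' @return An object of class `eeg_region_map`.
#' @seealso [default_region_map()]
#' @export
region_map <- function(regions, pairs) {
  if (!is.list(regions) || is.null(names(regions)) || any(names(regions) == ""))
    stop_input("`regions` must be a named list of channel label vectors.", "region_map")
  regions <- lapply(regions, canonical_label)
  region_names <- names(regions)
  if (anyDuplicated(region_names))
    stop_input("Region names must be unique.", "region_map")
  all_channels <- unlist(regions, use.names = FALSE)
  if (anyDuplicated(all_channels))
    stop_input("Each channel may belong to at most one region.", "region_map")
  pairs <- lapply(pairs, as.character)
  if (any(vapply(pairs, length, 1L) != 2L))
    stop_input("Each asymmetry pair must have exactly two region names.", "region_map")
  pair_members <- unlist(pairs)
  missing <- setdiff(pair_members, region_names)
  if (length(missing))
    stop_input(paste0("Pair members not in region list: ",
                      paste(missing, collapse = ", ")), "region_map")
  structure(
    list(regions = regions, region_names = region_names, pairs = pairs),
    class = "eeg_region_map"
  )
}

#' Default 32-channel, 14-region map
#'
#' Maps the standard 32-electrode 10-20/10-10 montage onto 5 lateral region
#' pairs (frontal, central, temporal, parietal, occipital) plus the 4 midline
#' zones Fz, Cz, Pz and Oz. All lateral pairs are asymmetry pairs. The map is
#' a package default, not a claim about any particular clinical study's
#' electrode grouping; supply your own [region_map()] to override it.
#'
#' @return An `eeg_region_map` with 14 regions and 5 pairs.
#' @export
default_region_map <- function() {
  region_map(
    regions = list(
      frontal_left    = c("FP1", "AF3", "F3", "F7"),
      frontal_right   = c("FP2", "AF4", "F4", "F8"),
      central_left    = c("FC1", "FC5", "C3"),
      central_right   = c("FC2", "FC6", "C4"),
      temporal_left   = "T7",
      temporal_right  = "T8",
      parietal_left   = c("CP1", "CP5", "P3", "P7", "PO3"),
      parietal_right  = c("CP2", "CP6", "P4", "P8", "PO4"),
      occipital_left  = "O1",
      occipital_right = "O2",
      midline_fz      = "FZ",
      midline_cz      = "CZ",
      midline_pz      = "PZ",
      midline_oz      = "OZ"
    ),
    pairs = list(
      c("frontal_left", "frontal_right"),
      c("central_left", "central_right"),
      c("temporal_left", "temporal_right"),
      c("parietal_left", "parietal_right"),
      c("occipital_left", "occipital_right")
    )
  )
}

#' Default 32-channel montage labels
#'
#' @return Character vector of the 32 channel labels used by
#'   [default_region_map()], in a conventional cap order.
#' @export
default_channel_labels <- function() {
  c("FP1", "AF3", "F7", "F3", "FZ", "FC1", "FC5", "T7", "C3", "CP1",
    "CP5", "P7", "P3", "PZ", "PO3", "O1", "OZ", "O2", "PO4", "P4",
    "P8", "CP6", "CP2", "C4", "T8", "FC6", "FC2", "F4", "F8", "AF4",
    "FP2", "CZ")
}

#' @export
print.eeg_region_map <- function(x, ...) {
  cat("<eeg_region_map>", length(x$region_names), "regions,",
      length(x$pairs), "asymmetry pairs\n")
  for (rn in x$region_names)
    cat("  ", format(rn, width = 16), paste(x$regions[[rn]], collapse = " "), "\n")
  invisible(x)
}

#' Read or write a region map as YAML
#'
#' The YAML layout is `regions: {name: [labels]}` and
#' `pairs: [[left, right], ...]`.
#'
#' @param path File path.
#' @param map An `eeg_region_map`.
#' @return `read_region_map()` returns an `eeg_region_map`;
#'   `write_region_map()` returns `path` invisibly.
#' @export
read_region_map <- function(path) {
  y <- yaml::read_yaml(path)
  region_map(regions = y$regions, pairs = y$pairs)
}

#' @rdname read_region_map
#' @export
write_region_map <- function(map, path) {
  stopifnot(inherits(map, "eeg_region_map"))
  yaml::write_yaml(list(regions = map$regions, pairs = map$pairs), path)
  invisible(path)
}

#' Match recording channels to regions
#'
#' Resolves a region map against the channels actually present in a
#' recording. Matching is by label, never by position, so channel order in
#' the file is irrelevant. Channels not named by the map (e.g. auxiliary
#' "ECG" leads) are excluded with a warning; a region with no channel present
#' is an error, since its features would be undefined.
#'
#' @param rec An `eeg_recording`.
#' @param map An `eeg_region_map`, default [default_region_map()].
#' @return Named list: region name -> integer indices into the recording's
#'   channel rows.
#' @export
validate_montage <- function(rec, map = default_region_map()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(map, "eeg_region_map"))
  labels <- canonical_label(rec$channel_labels)
  mapped <- lapply(map$regions, function(chs) which(labels %in% chs))
  empty <- map$region_names[vapply(mapped, length, 1L) == 0L]
  if (length(empty))
    stop_input(paste0("No channels present for region(s): ",
                      paste(empty, collapse = ", ")), "montage",
               regions = empty)
  used <- unlist(mapped, use.names = FALSE)
  extra <- setdiff(seq_along(labels), used)
  if (length(extra))
    warn(paste0("Unmapped channel(s) excluded from feature extraction: ",
                paste(labels[extra], collapse = ", ")),
         class = "eegresponse_warning_unmapped_channels")
  mapped
}
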