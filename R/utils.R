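# internal helpers: error classes and seed derivation

stop_input <- function(msg, class, ...) {
  abort(msg, class = c(paste0("eegresponse_error_", class), "eegresponse_error"), ...)
}

#' Derive a child seed from a master seed and stream identifiers
#'
#' Expands one master seed into independent per-subject / per-stage /
#' per-feature seeds by hashing integer coordinates with a splitmix-style
#' multiplicative mix. Results are kept in `[0, 2^31 - 2]` so they are valid
#' arguments to [set.seed()]. The scheme is order-independent: the seed for
#' subject 17 does not depend on how many subjects were generated before it.
#'
#' @param seed Master seed (single integer).
#' @param ... Further integer stream coordinates (e.g. subject index,
#'   repeat index, feature index).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(unlist(list(...))))
  h <- 0
  for (p in parts) {
    # 64-bit-safe mixing in double arithmetic (exact below 2^53)
    h <- (h * 69069 + (p %% 2147483647) * 40503 + 12345) %% 2147483647
    h <- (h * 48271) %% 2147483647
  }
  as.integer(h %% 2147483646)
}

# evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# canonical channel label form: uppercase, trimmed
canonical_label <- function(x) toupper(trimws(as.character(x)))

#' Hemisphere of a 10-20 channel label
#'
#' Standard 10-20/10-10 naming: odd terminal digit = left hemisphere, even =
#' right, trailing "Z" = midline. Labels that fit none of these (e.g. "ECG")
#' are classed as "unknown".
#'
#' @param label Character vector of channel labels.
#' @return Character vector: "left", "right", "midline" or "unknown".
#' @export
hemisphere_of <- function(label) {
  lab <- canonical_label(label)
  out <- rep("unknown", length(lab))
  out[grepl("^[A-Z]+Z$", lab)] <- "midline"
  digit <- suppressWarnings(as.integer(sub("^[A-Z]+([0-9]+)$", "\\1", lab)))
  has_digit <- grepl("^[A-Z]+[0-9]+$", lab)
  out[has_digit & digit %% 2 == 1] <- "left"
  out[has_digit & digit %% 2 == 0] <- "right"
  out
}
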