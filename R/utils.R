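# Internal helpers shared across modules.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

CHAIN_TYPES <- c("COL1A1", "COL1A2", "COL3A1")

#' Collapse isoleucine and leucine to a single symbol
#'
#' I and L are isobaric and indistinguishable by the MS/MS workflow this
#' package models, so peptide lookup and uniqueness reasoning treat them
#' as one residue. Stored sequences are never mutated; the collapse is
#' applied only when building keys.
#'
#' @param x character vector of peptide or protein sequences.
#' @return character vector with every I and L replaced by "J".
#' @examples
#' collapse_il(c("GIAGPK", "GLAGPK"))
#' @export
collapse_il <- function(x) {
  chartr("IL", "JJ", x)
}

# Validate a sequence against the 20-letter alphabet; returns the
# 1-based position of the first illegal character, or 0L if clean.
first_illegal_residue <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) == 0L) 0L else bad[1L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stopifnot-style check with a formatted message
check_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}
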