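# PSM table IO: read, validate and write evidence-style tables of
# peptide-spectrum matches with modification annotations.
#
# Table dialect (tab-separated, header mandatory):
#   sample_id  spectrum_id  peptide  modifications  charge  ion_score
#   intensity  accession  start
# The modifications column joins tokens with ";"; each token is
# "kind@pos" (1-based position within the peptide) or "kind@?" for an
# unlocalized event. Supported kinds: deamidation (N/Q), oxidation (M),
# hydroxylation (P/K). An empty string means no modification.

PSM_COLUMNS <- c("sample_id", "spectrum_id", "peptide", "modifications",
                 "charge", "ion_score", "intensity", "accession", "start")

MOD_KINDS <- c("deamidation", "oxidation", "hydroxylation")
MOD_ALLOWED <- list(deamidation = c("N", "Q"), oxidation = "M",
                    hydroxylation = c("P", "K"))

# Monoisotopic atomic masses (Da)
ATOMIC_MASS <- c(H = 1.0078250319, C = 12.0, N = 14.0030740052,
                 O = 15.9949146221, S = 31.97207069)

#' Monoisotopic mass delta of a modification
#'
#' Computed from monoisotopic atomic masses: deamidation replaces the
#' side-chain amide NH2 with OH, a net (O + H) - (N + 2H) = O - N - H;
#' oxidation and hydroxylation each add one oxygen.
#'
#' @param kind "deamidation", "oxidation" or "hydroxylation".
#' @return the mass shift in Da.
#' @examples
#' round(mod_mass_delta("deamidation"), 5)  # +0.98402
#' @export
mod_mass_delta <- function(kind) {
  m <- ATOMIC_MASS
  switch(kind,
         deamidation = unname((m["O"] + m["H"]) - (m["N"] + 2 * m["H"])),
         oxidation = unname(m["O"]),
         hydroxylation = unname(m["O"]),
         stop(sprintf("unknown modification kind '%s'", kind), call. = FALSE))
}

#' Parse a modification string
#'
#' @param spec the "kind@pos" dialect, ";"-joined; "" or NA means none.
#' @return data.frame with columns kind, position (NA for unlocalized).
#' @export
parse_modifications <- function(spec) {
  if (is.na(spec) || !nzchar(spec)) {
    return(data.frame(kind = character(0), position = integer(0)))
  }
  tokens <- strsplit(spec, ";", fixed = TRUE)[[1]]
  tokens <- trimws(tokens)
  kinds <- character(length(tokens)); pos <- integer(length(tokens))
  for (i in seq_along(tokens)) {
    parts <- strsplit(tokens[i], "@", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !parts[1] %in% MOD_KINDS ||
        !(parts[2] == "?" || grepl("^[0-9]+$", parts[2]))) {
      stop(sprintf("unparseable modification token '%s'", tokens[i]),
           call. = FALSE)
    }
    kinds[i] <- parts[1]
    pos[i] <- if (parts[2] == "?") NA_integer_ else as.integer(parts[2])
  }
  data.frame(kind = kinds, position = pos, stringsAsFactors = FALSE)
}

# Residue-rule check for one PSM row; returns NULL when valid, else a
# human-readable reason.
mod_violation <- function(peptide, mods) {
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(mods))) {
    kind <- mods$kind[i]; pos <- mods$position[i]
    allowed <- MOD_ALLOWED[[kind]]
    if (is.na(pos)) {
      if (!any(chars %in% allowed)) {
        return(sprintf("unlocalized %s but peptide has no %s residue",
                       kind, paste(allowed, collapse = "/")))
      }
    } else {
      if (pos < 1L || pos > length(chars)) {
        return(sprintf("%s@%d outside peptide of length %d", kind, pos,
                       length(chars)))
      }
      if (!chars[pos] %in% allowed) {
        return(sprintf("%s@%d targets '%s' (allowed: %s)", kind, pos,
                       chars[pos], paste(allowed, collapse = "/")))
      }
    }
  }
  NULL
}

#' Read and validate a PSM table
#'
#' Rows failing validation (bad modification placement, unverifiable
#' chain assignment, negative intensity) are collected into a rejected
#' set with reasons, never silently dropped. Chain assignments are
#' verified by substring match against the database under I/L collapse.
#'
#' @param path tab-separated file in the documented dialect.
#' @param db a "collagen_db" to verify assignments against; NULL skips
#'   assignment verification.
#' @return list with elements `psms` (accepted rows), `rejected` (rows
#'   plus a `reason` column), and `n_input`.
#' @export
read_psm_table <- function(path, db = NULL) {
  check_that(file.exists(path), "file not found: %s", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  missing <- setdiff(PSM_COLUMNS, names(tab))
  check_that(length(missing) == 0L, "missing mandatory column(s): %s",
             paste(missing, collapse = ", "))
  tab <- tab[, PSM_COLUMNS, drop = FALSE]
  tab$charge <- as.integer(tab$charge)
  tab$ion_score <- as.numeric(tab$ion_score)
  tab$intensity <- suppressWarnings(as.numeric(tab$intensity))
  tab$start <- as.integer(tab$start)
  tab$peptide <- toupper(tab$peptide)
  validate_psms(tab, db)
}

#' Validate an in-memory PSM data.frame
#'
#' @param tab data.frame with the PSM columns.
#' @param db optional "collagen_db" for assignment verification.
#' @return list(psms, rejected, n_input); see [read_psm_table()].
#' @export
validate_psms <- function(tab, db = NULL) {
  n <- nrow(tab)
  reasons <- character(n)
  seq_by_acc <- NULL
  if (!is.null(db)) {
    seq_by_acc <- stats::setNames(collapse_il(db$sequence), db$accession)
  }
  for (i in seq_len(n)) {
    pep <- tab$peptide[i]
    bad <- first_illegal_residue(pep)
    if (bad != 0L) {
      reasons[i] <- sprintf("illegal residue at peptide position %d", bad)
      next
    }
    mods <- tryCatch(parse_modifications(tab$modifications[i]),
                     error = function(e) e)
    if (inherits(mods, "error")) {
      stop(sprintf("row %d: %s", i, conditionMessage(mods)), call. = FALSE)
    }
    v <- mod_violation(pep, mods)
    if (!is.null(v)) { reasons[i] <- v; next }
    if (!is.na(tab$intensity[i]) && tab$intensity[i] < 0) {
      reasons[i] <- "negative intensity"
      next
    }
    if (!is.null(seq_by_acc)) {
      acc <- tab$accession[i]
      if (!acc %in% names(seq_by_acc)) {
        reasons[i] <- sprintf("unknown accession '%s'", acc)
        next
      }
      s <- tab$start[i]
      chain <- seq_by_acc[[acc]]
      if (is.na(s) || s < 1L || s + nchar(pep) - 1L > nchar(chain) ||
          substr(chain, s, s + nchar(pep) - 1L) != collapse_il(pep)) {
        reasons[i] <- sprintf(
          "peptide does not match chain '%s' at position %s", acc, s)
        next
      }
    }
  }
  ok <- !nzchar(reasons)
  rejected <- tab[!ok, , drop = FALSE]
  if (nrow(rejected) > 0) rejected$reason <- reasons[!ok]
  else rejected$reason <- character(0)
  rownames(rejected) <- NULL
  psms <- tab[ok, , drop = FALSE]
  rownames(psms) <- NULL
  list(psms = psms, rejected = rejected, n_input = n)
}

#' Write a PSM table
#'
#' @param psms accepted-PSM data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  out <- psms[, PSM_COLUMNS, drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
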