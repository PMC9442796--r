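# Backbone cleavage: semitryptic PSM fraction and site-specific
# modification-state maps.
#
# Nonenzymatic backbone hydrolysis during glue manufacture leaves
# peptides with a trypsin-conforming cleavage site at only one end
# (semitryptic). The cleavage index is the number of semitryptic PSMs
# divided by the total (fully tryptic plus semitryptic) PSMs of the
# scope, after an inclusive ion-score cutoff (default >= 25). PSMs with
# no trypsin-conforming terminus at all (nonspecific) cannot arise from
# a semitryptic search and are excluded from the ratio but reported for
# diagnostics.

#' Terminus specificity of a PSM on its chain
#'
#' The N-terminus is specific when the preceding chain residue is K/R
#' not followed by P, or when the peptide starts at position 1; the
#' C-terminus is specific when the last residue is K/R with the
#' following chain residue not P, or when the peptide ends at the chain
#' end.
#'
#' @param peptide peptide sequence.
#' @param chain_sequence full chain sequence.
#' @param start 1-based start of the peptide on the chain.
#' @param block_proline keep the proline block (default TRUE).
#' @return list(nterm_specific, cterm_specific, category) with category
#'   one of "fully_tryptic", "semitryptic", "nonspecific".
#' @export
terminus_specificity <- function(peptide, chain_sequence, start,
                                 block_proline = TRUE) {
  L <- nchar(chain_sequence)
  len <- nchar(peptide)
  end <- start + len - 1L
  check_that(start >= 1L && end <= L,
             "peptide [%d, %d] outside chain of length %d", start, end, L)
  check_that(substr(collapse_il(chain_sequence), start, end) ==
               collapse_il(peptide),
             "peptide does not match chain at position %d", start)
  is_site_after <- function(p) {
    # trypsin cleaves after position p
    r <- substr(chain_sequence, p, p)
    if (!r %in% c("K", "R")) return(FALSE)
    if (block_proline && p < L && substr(chain_sequence, p + 1L, p + 1L) == "P")
      return(FALSE)
    TRUE
  }
  nspec <- start == 1L || is_site_after(start - 1L)
  cspec <- end == L || is_site_after(end)
  category <- if (nspec && cspec) "fully_tryptic"
              else if (nspec || cspec) "semitryptic"
              else "nonspecific"
  list(nterm_specific = nspec, cterm_specific = cspec, category = category)
}

# Vectorized specificity categories for a PSM table against a db.
psm_categories <- function(psms, db) {
  seq_by_acc <- stats::setNames(db$sequence, db$accession)
  vapply(seq_len(nrow(psms)), function(i) {
    terminus_specificity(psms$peptide[i],
                         seq_by_acc[[psms$accession[i]]],
                         psms$start[i])$category
  }, character(1))
}

#' Semitryptic backbone-cleavage index
#'
#' @param psms accepted-PSM data.frame.
#' @param db a "collagen_db" (accessions of the PSMs must be present).
#' @param score_cutoff inclusive ion-score cutoff (default 25).
#' @param scope "chain" (per sample x species x chain) or "sample".
#' @return data.frame: sample_id, species, chain_type (NA for scope =
#'   "sample"), n_semitryptic, n_fully_tryptic, n_total (tryptic +
#'   semitryptic), n_nonspecific (excluded from the ratio), fraction.
#'   Scopes with zero qualifying PSMs are omitted.
#' @export
cleavage_index <- function(psms, db, score_cutoff = 25,
                           scope = c("chain", "sample")) {
  scope <- match.arg(scope)
  empty <- data.frame(sample_id = character(0), species = character(0),
                      chain_type = character(0), n_semitryptic = integer(0),
                      n_fully_tryptic = integer(0), n_total = integer(0),
                      n_nonspecific = integer(0), fraction = numeric(0))
  if (nrow(psms) == 0L) return(empty)
  psms <- psms[psms$ion_score >= score_cutoff, , drop = FALSE]
  if (nrow(psms) == 0L) return(empty)
  db_df <- as.data.frame(db)
  # restrict to the fibrillar type I / III chains
  db_df <- db_df[db_df$chain_type %in% CHAIN_TYPES, , drop = FALSE]
  psms <- psms[psms$accession %in% db_df$accession, , drop = FALSE]
  if (nrow(psms) == 0L) return(empty)
  cat <- psm_categories(psms, db_df)
  meta <- db_df[match(psms$accession, db_df$accession), ]
  if (scope == "chain") {
    grp <- interaction(psms$sample_id, meta$species, meta$chain_type,
                       drop = TRUE)
  } else {
    grp <- interaction(psms$sample_id, drop = TRUE)
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(psms)), grp), function(idx) {
    n_semi <- sum(cat[idx] == "semitryptic")
    n_full <- sum(cat[idx] == "fully_tryptic")
    n_non <- sum(cat[idx] == "nonspecific")
    n_tot <- n_semi + n_full
    if (n_tot == 0L) return(NULL)
    data.frame(sample_id = psms$sample_id[idx[1]],
               species = if (scope == "chain")
                 meta$species[idx[1]] else NA_character_,
               chain_type = if (scope == "chain")
                 meta$chain_type[idx[1]] else NA_character_,
               n_semitryptic = n_semi, n_fully_tryptic = n_full,
               n_total = n_tot, n_nonspecific = n_non,
               fraction = n_semi / n_tot, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) return(empty)
  out <- out[order(out$sample_id, out$species, out$chain_type), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Site-specific modification-state map of one chain
#'
#' Labels every N, Q and M position of the chain from the PSMs covering
#' it. N/Q states: "D" (seen only deamidated), "DX" (seen both ways),
#' "X" (seen only unmodified), "NF" (not covered). M states: "OX" (seen
#' only oxidized), "OXX" (seen both ways), "X", "NF". A PSM carrying an
#' unlocalized deamidation contributes deamidation evidence only when
#' the peptide has a single candidate N/Q site; otherwise it is
#' ambiguous and excluded from state calls (a position covered only by
#' ambiguous PSMs reports "NF").
#'
#' @param psms accepted-PSM data.frame; only rows assigned to `chain`'s
#'   accession are used.
#' @param chain one-row chain record.
#' @return data.frame: accession, position, residue, state, n_psms
#'   (PSMs contributing state evidence at the position).
#' @export
site_state_map <- function(psms, chain) {
  seqc <- if (is.data.frame(chain)) chain$sequence[1] else chain$sequence
  acc <- if (is.data.frame(chain)) chain$accession[1] else chain$accession
  chars <- strsplit(seqc, "", fixed = TRUE)[[1]]
  targets <- which(chars %in% c("N", "Q", "M"))
  n_mod <- integer(length(chars))     # modified observations per position
  n_unmod <- integer(length(chars))   # unmodified observations per position
  psms <- psms[psms$accession == acc, , drop = FALSE]
  for (i in seq_len(nrow(psms))) {
    pep <- psms$peptide[i]
    plen <- nchar(pep)
    s <- psms$start[i]; e <- s + plen - 1L
    check_that(s >= 1L && e <= length(chars),
               "PSM %d: position outside chain '%s'", i, acc)
    pchars <- strsplit(pep, "", fixed = TRUE)[[1]]
    mods <- parse_modifications(psms$modifications[i])
    deam <- mods[mods$kind == "deamidation", , drop = FALSE]
    oxid <- mods[mods$kind == "oxidation", , drop = FALSE]
    candidates <- which(pchars %in% c("N", "Q"))
    m_sites <- which(pchars == "M")
    ambiguous <- any(is.na(deam$position)) && length(candidates) > 1L
    ambiguous_m <- any(is.na(oxid$position)) && length(m_sites) > 1L
    mod_local <- rep(FALSE, plen)
    if (!ambiguous && nrow(deam) > 0L) {
      p <- deam$position
      p[is.na(p)] <- candidates[1L]   # single-candidate localization
      mod_local[p] <- TRUE
    }
    if (!ambiguous_m && nrow(oxid) > 0L) {
      p <- oxid$position
      p[is.na(p)] <- m_sites[1L]
      mod_local[p] <- TRUE
    }
    for (j in seq_len(plen)) {
      pos <- s + j - 1L
      if (!pchars[j] %in% c("N", "Q", "M")) next
      if (ambiguous && pchars[j] %in% c("N", "Q")) next
      if (ambiguous_m && pchars[j] == "M") next
      if (mod_local[j]) n_mod[pos] <- n_mod[pos] + 1L
      else n_unmod[pos] <- n_unmod[pos] + 1L
    }
  }
  state <- character(length(targets))
  for (k in seq_along(targets)) {
    pos <- targets[k]
    m <- n_mod[pos]; u <- n_unmod[pos]
    if (chars[pos] == "M") {
      state[k] <- if (m > 0 && u > 0) "OXX" else if (m > 0) "OX"
                  else if (u > 0) "X" else "NF"
    } else {
      state[k] <- if (m > 0 && u > 0) "DX" else if (m > 0) "D"
                  else if (u > 0) "X" else "NF"
    }
  }
  data.frame(accession = acc, position = targets,
             residue = chars[targets], state = state,
             n_psms = n_mod[targets] + n_unmod[targets],
             stringsAsFactors = FALSE)
}

#' Write a cleavage report
#'
#' @param idx output of [cleavage_index()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cleavage_report <- function(idx, path) {
  utils::write.table(idx, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a site-state map
#'
#' @param map output of [site_state_map()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
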