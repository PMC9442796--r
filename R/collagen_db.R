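# Collagen reference database: FASTA IO, validation, in-silico
# digestion and peptide-to-chain indexing.
#
# The database emulates a focused collagen search space: one entry per
# (species, chain) for the fibrillar collagen chains COL1A1, COL1A2 and
# COL3A1. Headers follow the dialect ">accession|species|chain_type".

#' Construct a collagen chain record
#'
#' @param accession opaque identifier, unique within a database.
#' @param species binomial species name, e.g. "Bos taurus".
#' @param chain_type one of "COL1A1", "COL1A2", "COL3A1".
#' @param sequence amino-acid sequence (20-letter alphabet); whitespace
#'   is stripped and the string uppercased.
#' @return a one-row data.frame with columns accession, species,
#'   chain_type, sequence, length.
#' @export
chain_record <- function(accession, species, chain_type, sequence) {
  sequence <- toupper(gsub("\\s+", "", sequence))
  check_that(nzchar(accession), "accession must be a nonempty string")
  check_that(nzchar(species), "species must be a nonempty string")
  check_that(chain_type %in% CHAIN_TYPES,
             "chain_type '%s' is not one of %s", chain_type,
             paste(CHAIN_TYPES, collapse = ", "))
  check_that(nzchar(sequence), "record '%s': sequence is empty", accession)
  bad <- first_illegal_residue(sequence)
  check_that(bad == 0L,
             "record '%s': illegal residue '%s' at position %d",
             accession, substr(sequence, bad, bad), bad)
  data.frame(accession = accession, species = species,
             chain_type = chain_type, sequence = sequence,
             length = nchar(sequence), stringsAsFactors = FALSE)
}

#' Assemble and validate a collagen database
#'
#' @param chains a data.frame of chain records (rows as produced by
#'   [chain_record()]) or a list of such one-row data.frames.
#' @return the validated data.frame with class "collagen_db".
#' @export
collagen_db <- function(chains) {
  if (is.list(chains) && !is.data.frame(chains)) {
    chains <- if (length(chains) == 0L) {
      data.frame(accession = character(0), species = character(0),
                 chain_type = character(0), sequence = character(0),
                 length = integer(0))
    } else {
      do.call(rbind, chains)
    }
  }
  check_that(is.data.frame(chains) && nrow(chains) >= 0,
             "chains must be a data.frame of chain records")
  if (nrow(chains) > 0) {
    dup_acc <- chains$accession[duplicated(chains$accession)]
    check_that(length(dup_acc) == 0L,
               "duplicate accession(s): %s", paste(unique(dup_acc), collapse = ", "))
    key <- paste(chains$species, chains$chain_type, sep = "/")
    dup <- key[duplicated(key)]
    check_that(length(dup) == 0L,
               "duplicate (species, chain_type) pair(s): %s",
               paste(unique(dup), collapse = ", "))
    for (i in seq_len(nrow(chains))) {
      check_that(chains$length[i] == nchar(chains$sequence[i]),
                 "record '%s': length field disagrees with sequence",
                 chains$accession[i])
    }
  }
  rownames(chains) <- NULL
  class(chains) <- c("collagen_db", "data.frame")
  chains
}

#' Read a collagen FASTA database
#'
#' Headers must follow ">accession|species|chain_type". Sequences are
#' uppercased and whitespace-stripped, then validated against the
#' 20-letter alphabet.
#'
#' @param path path to a FASTA file.
#' @return a "collagen_db" data.frame, one row per entry.
#' @export
read_collagen_fasta <- function(path) {
  check_that(file.exists(path), "file not found: %s", path)
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  records <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    fields <- strsplit(headers[i], "|", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (length(fields) != 3L || any(!nzchar(fields))) {
      stop(sprintf(
        "malformed FASTA header at entry %d: '>%s' (expected 'accession|species|chain_type')",
        i, headers[i]), call. = FALSE)
    }
    records[[i]] <- chain_record(fields[1], fields[2], fields[3],
                                 as.character(seqs[[i]]))
  }
  collagen_db(records)
}

#' Write a collagen database to FASTA
#'
#' @param db a "collagen_db".
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_collagen_fasta <- function(db, path) {
  seqs <- Biostrings::AAStringSet(db$sequence)
  names(seqs) <- paste(db$accession, db$species, db$chain_type, sep = "|")
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Write the database manifest
#'
#' Tab-separated summary (accession, species, chain, length), the
#' plain-text companion of the FASTA file.
#'
#' @param db a "collagen_db".
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_db_manifest <- function(db, path) {
  out <- data.frame(accession = db$accession, species = db$species,
                    chain = db$chain_type, length = db$length)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Positions p (1..L-1) after which trypsin cleaves: residue p is K or R
# and, when block_proline, residue p+1 is not P.
cleavage_sites <- function(sequence, block_proline = TRUE) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (L < 2L) return(integer(0))
  p <- which(chars[-L] %in% c("K", "R"))
  if (block_proline && length(p)) p <- p[chars[p + 1L] != "P"]
  p
}

#' In-silico tryptic or semitryptic digestion of one chain
#'
#' Trypsin cleaves C-terminal to K or R, blocked when the next residue
#' is proline (the block can be disabled). Protein termini always count
#' as specific ends. Tryptic mode returns every fully specific peptide
#' with at most `max_missed` internal cleavage sites; semitryptic mode
#' additionally returns every peptide with exactly one specific
#' terminus, under the same missed-cleavage bound counted over internal
#' K/R sites not followed by P.
#'
#' @param chain a one-row chain record (or any list with `sequence` and
#'   `accession`).
#' @param max_missed maximum number of missed cleavages (>= 0).
#' @param mode "tryptic" or "semitryptic".
#' @param block_proline logical; keep the proline block (default TRUE).
#' @return data.frame with columns sequence, accession, start, end,
#'   missed_cleavages, nterm_specific, cterm_specific. Coordinates are
#'   1-based inclusive on the parent chain.
#' @export
digest <- function(chain, max_missed = 3L, mode = c("tryptic", "semitryptic"),
                   block_proline = TRUE) {
  mode <- match.arg(mode)
  check_that(max_missed >= 0L, "max_missed must be >= 0")
  seq <- if (is.data.frame(chain)) chain$sequence[1] else chain$sequence
  acc <- if (is.data.frame(chain)) chain$accession[1] else chain$accession
  L <- nchar(seq)
  sites <- cleavage_sites(seq, block_proline)
  bounds <- c(0L, sites, L)
  # cumulative count of cleavage sites at positions 1..L
  ind <- integer(L)
  ind[sites] <- 1L
  cs <- c(0L, cumsum(ind))            # cs[p + 1] = #sites in 1..p
  missed_between <- function(s, e) cs[e] - cs[s]  # sites in [s, e-1]

  starts <- integer(0); ends <- integer(0)
  nspec <- logical(0); cspec <- logical(0)

  nb <- length(bounds)
  for (i in seq_len(nb - 1L)) {
    jmax <- min(nb, i + 1L + max_missed)
    for (j in (i + 1L):jmax) {
      starts <- c(starts, bounds[i] + 1L)
      ends <- c(ends, bounds[j])
      nspec <- c(nspec, TRUE); cspec <- c(cspec, TRUE)
    }
  }

  if (mode == "semitryptic") {
    is_bound <- c(rep(FALSE, L + 1L))
    is_bound[bounds + 1L] <- TRUE     # is_bound[p + 1] : p is a boundary
    for (i in seq_len(nb - 1L)) {     # specific N-terminus, ragged C
      s <- bounds[i] + 1L
      for (e in s:L) {
        if (is_bound[e + 1L]) next    # fully tryptic, already emitted
        if (missed_between(s, e) > max_missed) break
        starts <- c(starts, s); ends <- c(ends, e)
        nspec <- c(nspec, TRUE); cspec <- c(cspec, FALSE)
      }
    }
    for (j in 2L:nb) {                # specific C-terminus, ragged N
      e <- bounds[j]
      for (s in e:1L) {
        if (is_bound[s]) next         # s - 1 is a boundary
        if (missed_between(s, e) > max_missed) break
        starts <- c(starts, s); ends <- c(ends, e)
        nspec <- c(nspec, FALSE); cspec <- c(cspec, TRUE)
      }
    }
  }

  out <- data.frame(
    sequence = substring(seq, starts, ends),
    accession = rep(acc, length(starts)),
    start = starts, end = ends,
    missed_cleavages = cs[ends] - cs[starts],
    nterm_specific = nspec, cterm_specific = cspec,
    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a peptide-to-chain index
#'
#' Indexes the tryptic peptides of every chain under I/L equivalence:
#' lookup keys have I and L collapsed, stored sequences are untouched. A
#' peptide occurring in k chains has exactly k occurrence rows; a
#' peptide is unique when all its occurrences share one (species,
#' chain_type).
#'
#' @param db a "collagen_db".
#' @param max_missed missed-cleavage bound for the indexed digest.
#' @param block_proline keep the proline block (default TRUE).
#' @return an object of class "peptide_index".
#' @export
build_peptide_index <- function(db, max_missed = 3L, block_proline = TRUE) {
  db <- collagen_db(as.data.frame(db))   # revalidates uniqueness
  occ <- vector("list", nrow(db))
  for (i in seq_len(nrow(db))) {
    d <- digest(db[i, ], max_missed = max_missed, mode = "tryptic",
                block_proline = block_proline)
    if (nrow(d) == 0L) next
    occ[[i]] <- data.frame(
      key = collapse_il(d$sequence), sequence = d$sequence,
      accession = db$accession[i], species = db$species[i],
      chain_type = db$chain_type[i], start = d$start, end = d$end,
      missed_cleavages = d$missed_cleavages, stringsAsFactors = FALSE)
  }
  occ <- do.call(rbind, occ)
  if (is.null(occ)) {
    occ <- data.frame(key = character(0), sequence = character(0),
                      accession = character(0), species = character(0),
                      chain_type = character(0), start = integer(0),
                      end = integer(0), missed_cleavages = integer(0))
  }
  structure(list(occurrences = occ, max_missed = max_missed,
                 block_proline = block_proline, db = db),
            class = "peptide_index")
}

#' Look up a peptide in the index
#'
#' @param index a "peptide_index".
#' @param peptide peptide sequence; I/L collapse is applied before
#'   lookup, so "GIAGPK" and "GLAGPK" hit the same occurrences.
#' @return data.frame of occurrences (possibly empty) with an
#'   `is_unique` attribute-free column appended: TRUE when every
#'   occurrence shares one (species, chain_type).
#' @export
lookup_peptide <- function(index, peptide) {
  key <- collapse_il(peptide)
  hits <- index$occurrences[index$occurrences$key == key, , drop = FALSE]
  rownames(hits) <- NULL
  if (nrow(hits) > 0) {
    chains <- unique(paste(hits$species, hits$chain_type, sep = "/"))
    hits$is_unique <- length(chains) == 1L
  } else {
    hits$is_unique <- logical(0)
  }
  hits
}

#' @export
print.peptide_index <- function(x, ...) {
  cat(sprintf("peptide_index: %d occurrences of %d distinct peptides over %d chains\n",
              nrow(x$occurrences), length(unique(x$occurrences$key)),
              nrow(x$db)))
  invisible(x)
}
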