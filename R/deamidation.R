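# Deamidation quantification at peptide, chain, family and sample
# level.
#
# Occupancy convention: per PSM, occupancy = (number of deamidation
# events on residues of the class) / (number of residues of that class
# in the peptide). The peptide-level fraction is the intensity-weighted
# mean of PSM occupancies; when any contributing intensity is missing
# the weighting falls back to plain PSM counting and the fallback is
# recorded in `weight_basis`. Chain/family/sample summaries are
# unweighted means across peptide fractions, reported in percent with
# SD and the number of contributing peptides, asparagine (N) and
# glutamine (Q) always separate: Asn deamidation is fast and therefore
# usually less informative than Gln deamidation.
#
# Unlocalized deamidation events ("deamidation@?") are counted toward
# a residue class only when every candidate N/Q in the peptide belongs
# to that single class; otherwise the event is ambiguous and excluded
# from occupancy.

count_residue <- function(peptide, residue) {
  vapply(strsplit(peptide, "", fixed = TRUE),
         function(ch) sum(ch == residue), integer(1))
}

# Number of deamidation events attributable to `residue_class` for one
# PSM row.
deamidation_events <- function(peptide, modstring, residue_class) {
  mods <- parse_modifications(modstring)
  mods <- mods[mods$kind == "deamidation", , drop = FALSE]
  if (nrow(mods) == 0L) return(0L)
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  n <- 0L
  candidates <- unique(chars[chars %in% c("N", "Q")])
  for (i in seq_len(nrow(mods))) {
    pos <- mods$position[i]
    if (is.na(pos)) {
      # unlocalized: attributable only when unambiguous
      if (identical(candidates, residue_class)) n <- n + 1L
    } else if (chars[pos] == residue_class) {
      n <- n + 1L
    }
  }
  n
}

#' Peptide-level deamidation fraction
#'
#' @param psms PSM rows sharing one peptide key (I/L-collapsed).
#' @param residue_class "N" or "Q"; must occur in the peptide.
#' @return one-row data.frame: peptide (collapsed key), residue_class,
#'   n_sites, fraction in `[0, 1]`, weight_basis ("intensity" or
#'   "psm_count"), n_psms.
#' @export
peptide_deamidation <- function(psms, residue_class = c("Q", "N")) {
  residue_class <- match.arg(residue_class)
  keys <- unique(collapse_il(psms$peptide))
  check_that(length(keys) == 1L,
             "all PSMs must share one peptide key; got %d", length(keys))
  n_sites <- count_residue(psms$peptide[1], residue_class)
  check_that(n_sites >= 1L, "peptide '%s' has no %s residue",
             psms$peptide[1], residue_class)
  occ <- vapply(seq_len(nrow(psms)), function(i) {
    deamidation_events(psms$peptide[i], psms$modifications[i],
                       residue_class) / n_sites
  }, numeric(1))
  use_intensity <- !any(is.na(psms$intensity)) && sum(psms$intensity) > 0
  if (use_intensity) {
    fraction <- sum(occ * psms$intensity) / sum(psms$intensity)
    basis <- "intensity"
  } else {
    fraction <- mean(occ)
    basis <- "psm_count"
  }
  data.frame(peptide = keys, residue_class = residue_class,
             n_sites = n_sites, fraction = fraction,
             weight_basis = basis, n_psms = nrow(psms),
             stringsAsFactors = FALSE)
}

# Peptide-level fractions for every (sample, peptide key, class) in a
# PSM table. Vectorized work-horse of summarize_deamidation; must give
# the same result as per-group peptide_deamidation() calls.
peptide_fractions <- function(psms) {
  empty <- data.frame(sample_id = character(0), peptide = character(0),
                      residue_class = character(0), n_sites = integer(0),
                      fraction = numeric(0), weight_basis = character(0),
                      n_psms = integer(0))
  if (nrow(psms) == 0L) return(empty)
  n <- nrow(psms)
  pep <- psms$peptide
  n_of <- function(res) nchar(pep) - nchar(gsub(res, "", pep, fixed = TRUE))
  nN <- n_of("N"); nQ <- n_of("Q")

  # deamidation events per PSM and class, from the mod strings
  evN <- integer(n); evQ <- integer(n)
  has_mod <- !is.na(psms$modifications) & nzchar(psms$modifications)
  if (any(has_mod)) {
    toks <- strsplit(psms$modifications[has_mod], ";", fixed = TRUE)
    idx <- rep(which(has_mod), lengths(toks))
    tok <- trimws(unlist(toks))
    deam <- startsWith(tok, "deamidation@")
    idx <- idx[deam]; tok <- tok[deam]
    poss <- substring(tok, nchar("deamidation@") + 1L)
    unloc <- poss == "?"
    # localized events: classify by the residue at the stated position
    li <- idx[!unloc]; lp <- as.integer(poss[!unloc])
    res <- substr(pep[li], lp, lp)
    if (length(li)) {
      evN <- evN + tabulate(li[res == "N"], nbins = n)
      evQ <- evQ + tabulate(li[res == "Q"], nbins = n)
    }
    # unlocalized events: attributable only when one class is present
    ui <- idx[unloc]
    if (length(ui)) {
      evN <- evN + tabulate(ui[nN[ui] > 0L & nQ[ui] == 0L], nbins = n)
      evQ <- evQ + tabulate(ui[nQ[ui] > 0L & nN[ui] == 0L], nbins = n)
    }
  }

  key <- collapse_il(pep)
  grp <- paste(psms$sample_id, key, sep = "\r")
  gid <- match(grp, unique(grp))
  ng <- max(gid)
  first <- match(seq_len(ng), gid)
  na_int <- as.logical(rowsum(as.numeric(is.na(psms$intensity)), gid) > 0)
  int_sum <- rowsum(ifelse(is.na(psms$intensity), 0, psms$intensity), gid)
  w <- ifelse(na_int[gid] | int_sum[gid] <= 0, 1, psms$intensity)
  wsum <- as.numeric(rowsum(w, gid))
  n_psms <- as.integer(tabulate(gid, nbins = ng))
  basis <- ifelse(na_int | int_sum <= 0, "psm_count", "intensity")

  build <- function(cls, ev, nsite) {
    keep <- which(nsite[first] > 0L)
    if (length(keep) == 0L) return(empty)
    occ <- ifelse(nsite > 0L, ev / pmax(nsite, 1L), 0)
    frac <- as.numeric(rowsum(w * occ, gid)) / wsum
    data.frame(sample_id = psms$sample_id[first][keep],
               peptide = key[first][keep], residue_class = cls,
               n_sites = nsite[first][keep], fraction = frac[keep],
               weight_basis = basis[keep], n_psms = n_psms[keep],
               stringsAsFactors = FALSE)
  }
  res <- rbind(build("N", evN, nN), build("Q", evQ, nQ))
  rownames(res) <- NULL
  res
}

#' Summarize deamidation per chain, protein family, or sample
#'
#' Scopes: "chain" groups peptides by (species, chain_type); "family"
#' pools homologous chain types across species (e.g. all COL1A1
#' regardless of the animal); "global" pools every peptide of the
#' sample. A peptide key is counted once per scope group even when it
#' maps to several chains inside the group.
#'
#' @param psms accepted-PSM data.frame.
#' @param db a "collagen_db" or prebuilt "peptide_index" used to assign
#'   peptides to chains.
#' @param scope "chain", "family" or "global".
#' @return data.frame: sample_id, scope, species (NA unless scope =
#'   "chain"), chain_type (NA for "global"), residue_class,
#'   mean_fraction and sd in percent (sd NA when n_peptides < 2),
#'   n_peptides, weight_basis.
#' @export
summarize_deamidation <- function(psms, db,
                                  scope = c("chain", "family", "global")) {
  scope <- match.arg(scope)
  index <- if (inherits(db, "peptide_index")) db else build_peptide_index(db)
  fr <- peptide_fractions(psms)
  if (nrow(fr) == 0L) {
    return(data.frame(sample_id = character(0), scope = character(0),
                      species = character(0), chain_type = character(0),
                      residue_class = character(0), mean_fraction = numeric(0),
                      sd = numeric(0), n_peptides = integer(0),
                      weight_basis = character(0)))
  }
  occ <- index$occurrences
  if (scope == "global") {
    fr$species <- NA_character_; fr$chain_type <- NA_character_
    assigned <- fr
  } else {
    map <- unique(occ[, c("key", "species", "chain_type")])
    if (scope == "family") {
      map <- unique(map[, c("key", "chain_type")])
      map$species <- NA_character_
    }
    assigned <- merge(fr, map, by.x = "peptide", by.y = "key")
    # one row per (sample, peptide, class, scope group)
    g <- paste(assigned$sample_id, assigned$peptide, assigned$residue_class,
               assigned$species, assigned$chain_type, sep = "\r")
    assigned <- assigned[!duplicated(g), , drop = FALSE]
  }
  grp <- paste(assigned$sample_id, assigned$species, assigned$chain_type,
               assigned$residue_class, sep = "\r")
  out <- do.call(rbind, lapply(split(assigned, grp), function(a) {
    data.frame(sample_id = a$sample_id[1], scope = scope,
               species = a$species[1], chain_type = a$chain_type[1],
               residue_class = a$residue_class[1],
               mean_fraction = 100 * mean(a$fraction),
               sd = if (nrow(a) >= 2L) 100 * stats::sd(a$fraction) else NA_real_,
               n_peptides = nrow(a),
               weight_basis = if (all(a$weight_basis == "intensity"))
                 "intensity" else "psm_count",
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$sample_id, out$residue_class, out$species,
                   out$chain_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Order deamidation summaries for comparison
#'
#' Sorts summaries of one residue class by mean fraction (ascending)
#' so group contrasts (pure vs. mixed, hide vs. bone) can be read off
#' directly; ties break deterministically on the scope labels.
#'
#' @param summaries output rows of [summarize_deamidation()], one
#'   residue class.
#' @param groups optional character vector (recycled) of group labels,
#'   e.g. tissue/purity, carried into the output.
#' @return the summaries, sorted, with a `rank` column (1 = least
#'   deamidated) and optional `group`.
#' @export
compare_scopes <- function(summaries, groups = NULL) {
  cls <- unique(summaries$residue_class)
  check_that(length(cls) == 1L,
             "compare_scopes expects a single residue class; got: %s",
             paste(cls, collapse = ", "))
  if (!is.null(groups)) summaries$group <- rep(groups, length.out = nrow(summaries))
  tie <- paste(summaries$sample_id, summaries$species, summaries$chain_type)
  o <- order(summaries$mean_fraction, tie)
  out <- summaries[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write a deamidation summary table
#'
#' Tab-separated mirror of the per-chain deamidation report (sample,
#' scope, species, chain, residue, mean %, sd %, n peptides).
#'
#' @param summaries output of [summarize_deamidation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_deamidation_summary <- function(summaries, path) {
  utils::write.table(summaries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
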