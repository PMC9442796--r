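# Protein/species inference from PSMs and rule-based glue
# classification.
#
# A collagen chain is accepted for a sample when at least 2 different
# nonoverlapping peptides exceed the ion-score threshold (default 40,
# strict). "Nonoverlapping" means positionally disjoint intervals on
# the chain; the maximum disjoint count is found by earliest-end
# interval scheduling, which is optimal for intervals. Tissue calls:
# any accepted fish species makes the sample fish-mixed; otherwise
# collagen alpha-1(III) accepted for any species marks a hide glue
# (type III collagen is abundant in skin/connective tissue and poorly
# synthesized in bone); otherwise bone. Purity: pure when exactly one
# source species is accepted.

# Species vocabulary used by the matrix classifier: the common
# domesticates of collagen-glue manufacture plus fish taxa.
MAMMAL_SPECIES <- c("Bos taurus", "Sus scrofa", "Oryctolagus cuniculus",
                    "Ovis aries", "Capra hircus", "Equus asinus",
                    "Equus caballus", "Cervus elaphus")
FISH_SPECIES <- c("Scyliorhinus canicula", "Acipenser sturio",
                  "Gadus morhua", "Cyprinus carpio")

#' Default fish taxa
#'
#' The cartilaginous/bony-fish species the classifier treats as fish
#' sources. Override via the `fish_taxa` argument of the classifiers.
#'
#' @return character vector of binomial names.
#' @export
default_fish_taxa <- function() FISH_SPECIES

# Maximum number of pairwise disjoint distinct peptides. Each distinct
# peptide key contributes one interval (its earliest occurrence on the
# chain, so a repeated peptide never counts twice), then earliest-end
# greedy interval scheduling, which is optimal for plain intervals.
max_disjoint_peptides <- function(start, end, key) {
  if (length(start) == 0L) return(0L)
  o <- order(start, end)
  start <- start[o]; end <- end[o]; key <- key[o]
  keep <- !duplicated(key)
  start <- start[keep]; end <- end[keep]
  o <- order(end, start)
  start <- start[o]; end <- end[o]
  last_end <- 0L; n <- 0L
  for (i in seq_along(start)) {
    if (start[i] > last_end) {
      n <- n + 1L
      last_end <- end[i]
    }
  }
  n
}

#' Infer chain-level evidence from PSMs
#'
#' Each PSM contributes to every (species, chain) its peptide matches
#' in the database under I/L collapse; peptides matching more than one
#' chain are flagged shared. Per (sample, species, chain) the evidence
#' is the maximum number of positionally disjoint distinct peptides
#' with ion score strictly above the threshold; a chain is accepted
#' when that count is at least 2.
#'
#' @param psms accepted-PSM data.frame (see [read_psm_table()]).
#' @param db a "collagen_db", or a prebuilt "peptide_index".
#' @param score_threshold ion-score cutoff, exclusive (default 40).
#' @return data.frame, one row per (sample_id, species, chain_type):
#'   columns n_peptides, n_nonoverlapping, n_shared, best_score,
#'   accepted.
#' @export
infer_chains <- function(psms, db, score_threshold = 40) {
  index <- if (inherits(db, "peptide_index")) db else build_peptide_index(db)
  empty <- data.frame(sample_id = character(0), species = character(0),
                      chain_type = character(0), n_peptides = integer(0),
                      n_nonoverlapping = integer(0), n_shared = integer(0),
                      best_score = numeric(0), accepted = logical(0))
  if (nrow(psms) == 0L) return(empty)
  keep <- psms$ion_score > score_threshold
  psms <- psms[keep, , drop = FALSE]
  if (nrow(psms) == 0L) return(empty)

  # best score per (sample, peptide key)
  key <- collapse_il(psms$peptide)
  grp <- paste(psms$sample_id, key, sep = "\r")
  best <- tapply(psms$ion_score, grp, max)
  uniq <- !duplicated(grp)
  pep <- data.frame(sample_id = psms$sample_id[uniq], key = key[uniq],
                    best_score = as.numeric(best[grp[uniq]]),
                    stringsAsFactors = FALSE)

  occ <- index$occurrences
  hits <- merge(pep, occ, by = "key")
  if (nrow(hits) == 0L) return(empty)
  nchains_per_key <- tapply(paste(occ$species, occ$chain_type),
                            occ$key, function(x) length(unique(x)))
  hits$shared <- as.integer(nchains_per_key[hits$key]) > 1L

  grp2 <- interaction(hits$sample_id, hits$species, hits$chain_type,
                      drop = TRUE)
  rows <- lapply(split(hits, grp2), function(h) {
    data.frame(sample_id = h$sample_id[1], species = h$species[1],
               chain_type = h$chain_type[1],
               n_peptides = length(unique(h$key)),
               n_nonoverlapping = max_disjoint_peptides(h$start, h$end, h$key),
               n_shared = length(unique(h$key[h$shared])),
               best_score = max(h$best_score),
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  ev$accepted <- ev$n_nonoverlapping >= 2L
  ev <- ev[order(ev$sample_id, ev$species, ev$chain_type), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# Core tissue/purity rules applied to a per-species detection table
# with logical columns COL1A1, COL1A2, COL3A1.
classify_species_table <- function(sample_id, det, fish_taxa) {
  det <- det[det$COL1A1 | det$COL1A2 | det$COL3A1, , drop = FALSE]
  species <- unique(det$species)
  if (length(species) == 0L) {
    return(data.frame(sample_id = sample_id, tissue = "unclassified",
                      purity = NA_character_, label = NA_character_,
                      n_species = 0L, species = "",
                      stringsAsFactors = FALSE))
  }
  any_fish <- any(species %in% fish_taxa)
  any_col3 <- any(det$COL3A1 & !det$species %in% fish_taxa)
  tissue <- if (any_fish) "fish-mixed" else if (any_col3) "hide" else "bone"
  purity <- if (length(species) == 1L) "pure" else "mixed"
  label <- switch(tissue,
                  "fish-mixed" = "FM",
                  hide = if (purity == "pure") "HP" else "HM",
                  bone = if (purity == "pure") "BP" else "BM")
  data.frame(sample_id = sample_id, tissue = tissue, purity = purity,
             label = label, n_species = length(species),
             species = paste(sort(species), collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Classify a glue sample from chain evidence
#'
#' @param evidence output of [infer_chains()] for one sample.
#' @param fish_taxa species treated as fish sources (default
#'   [default_fish_taxa()]).
#' @return one-row data.frame: sample_id, tissue (hide / bone /
#'   fish-mixed / unclassified), purity (pure / mixed / NA), label (HP,
#'   HM, BP, BM, FM), n_species, species (";"-joined).
#' @export
classify_glue <- function(evidence, fish_taxa = default_fish_taxa()) {
  sample_id <- unique(evidence$sample_id)
  check_that(length(sample_id) <= 1L,
             "classify_glue expects evidence for a single sample; got %d",
             length(sample_id))
  if (length(sample_id) == 0L) sample_id <- NA_character_
  acc <- evidence[evidence$accepted, , drop = FALSE]
  det <- data.frame(species = unique(acc$species), stringsAsFactors = FALSE)
  for (ct in CHAIN_TYPES) {
    det[[ct]] <- vapply(det$species, function(sp) {
      any(acc$chain_type[acc$species == sp] == ct)
    }, logical(1))
  }
  classify_species_table(sample_id, det, fish_taxa)
}

#' Classify samples from a chain-detection matrix
#'
#' Applies the same tissue/purity rules as [classify_glue()] to a
#' transcribed detection matrix (one row per sample x species, yes/no
#' chain flags), taking detections at face value with no score filter.
#'
#' @param mat data.frame with columns sample, species, col1a1, col1a2,
#'   col3a1 (logical, or "yes"/"no" strings).
#' @param fish_taxa species treated as fish sources.
#' @param known_species vocabulary used to catch typos; species outside
#'   it raise an error listing the offenders.
#' @return data.frame with one row per sample (columns as in
#'   [classify_glue()]).
#' @export
classify_from_matrix <- function(mat, fish_taxa = default_fish_taxa(),
                                 known_species = c(MAMMAL_SPECIES,
                                                   FISH_SPECIES)) {
  need <- c("sample", "species", "col1a1", "col1a2", "col3a1")
  missing <- setdiff(need, names(mat))
  check_that(length(missing) == 0L, "missing column(s): %s",
             paste(missing, collapse = ", "))
  unknown <- setdiff(unique(mat$species), known_species)
  check_that(length(unknown) == 0L, "unknown species: %s",
             paste(unknown, collapse = ", "))
  as_flag <- function(x) {
    if (is.logical(x)) return(!is.na(x) & x)
    tolower(trimws(as.character(x))) %in% c("yes", "y", "true", "1")
  }
  det_all <- data.frame(sample = mat$sample, species = mat$species,
                        COL1A1 = as_flag(mat$col1a1),
                        COL1A2 = as_flag(mat$col1a2),
                        COL3A1 = as_flag(mat$col3a1),
                        stringsAsFactors = FALSE)
  # merge duplicate (sample, species) rows by union of flags
  grp <- interaction(det_all$sample, det_all$species, drop = TRUE)
  det_all <- do.call(rbind, lapply(split(det_all, grp), function(d) {
    data.frame(sample = d$sample[1], species = d$species[1],
               COL1A1 = any(d$COL1A1), COL1A2 = any(d$COL1A2),
               COL3A1 = any(d$COL3A1), stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, lapply(split(det_all, det_all$sample), function(d) {
    classify_species_table(d$sample[1], d[, -1, drop = FALSE], fish_taxa)
  }))
  out <- out[order(out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a chain-detection matrix from a tab-separated file
#'
#' @param path TSV with columns sample, label (optional), species,
#'   col1a1, col1a2, col3a1.
#' @return data.frame as read.
#' @export
read_detection_matrix <- function(path) {
  check_that(file.exists(path), "file not found: %s", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a classification report
#'
#' @param cls classification data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(cls, path) {
  utils::write.table(cls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
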