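# Shared fixtures and independent oracles, built in code.

# Brute-force digestion oracle: enumerate every substring and keep the
# ones satisfying the trypsin specificity / missed-cleavage predicate.
# Independent of digest()'s boundary-pair construction.
brute_digest <- function(sequence, max_missed, mode, block_proline = TRUE) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  sites <- which(chars %in% c("K", "R"))
  sites <- sites[sites < L]
  if (block_proline) sites <- sites[chars[sites + 1L] != "P"]
  rows <- list()
  for (s in 1:L) for (e in s:L) {
    nspec <- s == 1L || (s - 1L) %in% sites
    cspec <- e == L || e %in% sites
    missed <- sum(sites >= s & sites <= e - 1L)
    if (missed > max_missed) next
    keep <- if (mode == "tryptic") nspec && cspec else nspec || cspec
    if (keep) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = s, end = e, nterm_specific = nspec,
        cterm_specific = cspec, missed_cleavages = missed)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random protein-like sequence with plenty of K/R/P so the proline
# block and missed-cleavage logic are exercised.
random_sequence <- function(len) {
  alphabet <- c("G", "P", "A", "K", "R", "N", "Q", "M", "S", "E", "D", "L", "I")
  weights <- c(3, 2.5, 2, 1.5, 1.5, 1, 1, 0.5, 1, 1, 1, 1, 1)
  paste(sample(alphabet, len, replace = TRUE, prob = weights),
        collapse = "")
}

# Two-chain toy database used across modules.
toy_db <- function() {
  collagen_db(list(
    chain_record("B1", "Bos taurus", "COL1A1", "GPAGNKGDQGRGPMGNR"),
    chain_record("S1", "Sus scrofa", "COL1A1", "GPAGNKGDQGRGAMGPR")))
}

# Minimal PSM row builder in the standard table layout.
make_psm <- function(sample_id, peptide, accession, start,
                     modifications = "", ion_score = 60,
                     intensity = 1e6, charge = 2L,
                     spectrum_id = NULL) {
  data.frame(sample_id = sample_id,
             spectrum_id = spectrum_id %||%
               sprintf("scan%05d", sample.int(99999L, 1L)),
             peptide = peptide, modifications = modifications,
             charge = charge, ion_score = ion_score,
             intensity = intensity, accession = accession,
             start = start, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

table2_path <- function() {
  system.file("extdata", "table2.tsv", package = "collaglue")
}

# Brute-force maximum independent set of intervals by subset
# enumeration; the oracle for the greedy disjoint count after the
# one-interval-per-peptide reduction.
brute_max_disjoint <- function(start, end) {
  n <- length(start)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(sel) <= best) next
    ok <- TRUE
    if (length(sel) > 1) {
      for (i in seq_along(sel)[-1]) for (j in seq_len(i - 1)) {
        a <- sel[i]; b <- sel[j]
        if (start[a] <= end[b] && start[b] <= end[a]) { ok <- FALSE; break }
      }
    }
    if (ok) best <- length(sel)
  }
  best
}
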