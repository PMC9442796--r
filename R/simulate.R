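# Synthetic collagen chains and PSM tables with known ground truth.
#
# The generator emulates the degradation phenomenology the estimators
# are built to measure: Gly-X-Y collagen repeats with high Pro content,
# tryptic peptides with up to 3 missed cleavages, per-site Bernoulli
# deamidation (N and Q separately), a configurable probability of one
# nonspecific terminus (backbone hydrolysis), Bernoulli methionine
# oxidation, log-normal intensities and ion scores straddling the
# 25/40 thresholds. Every draw is recorded in a truth ledger so each
# estimator can be checked against the generating parameters.

# Residue weights for the X and Y positions of the Gly-X-Y repeat.
# Proline-enriched X, Pro/Ala-enriched Y; N, Q and M are placed at
# appreciable rates so deamidation and oxidation estimators always
# have sites to work with. Hydroxyproline is not encoded in sequences
# (hydroxylation is a PSM-level modification only).
X_WEIGHTS <- c(P = 0.40, Q = 0.12, A = 0.10, E = 0.09, N = 0.07,
               L = 0.05, D = 0.05, S = 0.04, V = 0.03, M = 0.03,
               F = 0.02)
Y_WEIGHTS <- c(P = 0.30, A = 0.20, Q = 0.12, N = 0.08, E = 0.08,
               S = 0.07, M = 0.05, T = 0.05, V = 0.05)

#' Simulation configuration
#'
#' @param seed mandatory integer seed; all outputs are reproducible
#'   functions of it.
#' @param species species simulated (each gets COL1A1, COL1A2, COL3A1).
#' @param chain_length residues per chain; must be a multiple of 3 and
#'   at least 30.
#' @param kr_rate probability that a Y position carries K or R (sets
#'   tryptic site density).
#' @param deamidation_rate_n,deamidation_rate_q per-site Bernoulli
#'   deamidation probabilities for N and Q.
#' @param semitryptic_prob probability that an emitted PSM has exactly
#'   one nonspecific terminus (backbone hydrolysis).
#' @param oxidation_rate per-site Bernoulli oxidation probability for M.
#' @param intensity_meanlog,intensity_sdlog log-normal intensity
#'   parameters.
#' @param score_mean,score_sd normal ion-score parameters (clipped at
#'   0); defaults straddle the 25 and 40 thresholds.
#' @param n_psms PSMs per sample.
#' @param max_missed missed-cleavage bound of the sampled digest.
#' @param unassignable_fraction fraction of PSMs given a shuffled decoy
#'   peptide that fails chain verification.
#' @param samples data.frame of per-sample overrides (column sample_id
#'   plus any of n_psms, semitryptic_prob, deamidation_rate_n,
#'   deamidation_rate_q, oxidation_rate), or a character vector of
#'   sample ids; default one sample "S1" at the global parameters.
#' @return list of class "sim_config".
#' @export
simulation_config <- function(seed,
                              species = c("Bos taurus", "Sus scrofa"),
                              chain_length = 501L,
                              kr_rate = 0.22,
                              deamidation_rate_n = 0.5,
                              deamidation_rate_q = 0.35,
                              semitryptic_prob = 0.2,
                              oxidation_rate = 0.8,
                              intensity_meanlog = 14,
                              intensity_sdlog = 1,
                              score_mean = 45,
                              score_sd = 18,
                              n_psms = 500L,
                              max_missed = 3L,
                              unassignable_fraction = 0,
                              samples = "S1") {
  check_that(!missing(seed) && is.numeric(seed) && length(seed) == 1L,
             "seed is mandatory")
  check_that(chain_length %% 3 == 0 && chain_length >= 30,
             "chain_length must be a multiple of 3 and >= 30")
  probs <- c(kr_rate, deamidation_rate_n, deamidation_rate_q,
             semitryptic_prob, oxidation_rate, unassignable_fraction)
  check_that(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  if (is.character(samples)) {
    samples <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  }
  check_that(is.data.frame(samples) && "sample_id" %in% names(samples),
             "samples must name a sample_id column")
  cfg <- list(seed = as.integer(seed), species = species,
              chain_length = as.integer(chain_length), kr_rate = kr_rate,
              deamidation_rate_n = deamidation_rate_n,
              deamidation_rate_q = deamidation_rate_q,
              semitryptic_prob = semitryptic_prob,
              oxidation_rate = oxidation_rate,
              intensity_meanlog = intensity_meanlog,
              intensity_sdlog = intensity_sdlog,
              score_mean = score_mean, score_sd = score_sd,
              n_psms = as.integer(n_psms), max_missed = as.integer(max_missed),
              unassignable_fraction = unassignable_fraction,
              samples = samples)
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic small hash of a string, for per-chain subseeds.
str_hash <- function(s) {
  v <- utf8ToInt(s)
  sum(v * seq_along(v)) %% 1000003L
}

sample_param <- function(cfg, row, name) {
  if (name %in% names(cfg$samples)) {
    v <- cfg$samples[[name]][row]
    if (!is.na(v)) return(v)
  }
  cfg[[name]]
}

#' Generate one collagen-like chain
#'
#' Gly-X-Y triplets: position 1 of every triplet is G; X is drawn with
#' Pro-enriched weights; Y with Pro/Ala-enriched weights, replaced by K
#' or R at rate `kr_rate` to create tryptic sites. Glycine content is
#' exactly one third by construction. Deterministic in (seed, species,
#' chain_type).
#'
#' @param config a "sim_config".
#' @param species,chain_type identity of the chain.
#' @return a one-row chain record (see [chain_record()]).
#' @export
generate_chain <- function(config, species, chain_type) {
  check_that(config$chain_length %% 3 == 0,
             "chain length must be a multiple of 3")
  subseed <- (config$seed * 97L + str_hash(paste(species, chain_type))) %%
    2147483L
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(subseed)
  n_triplets <- config$chain_length %/% 3L
  x <- sample(names(X_WEIGHTS), n_triplets, replace = TRUE,
              prob = X_WEIGHTS)
  y <- sample(names(Y_WEIGHTS), n_triplets, replace = TRUE,
              prob = Y_WEIGHTS)
  is_kr <- stats::runif(n_triplets) < config$kr_rate
  y[is_kr] <- sample(c("K", "R"), sum(is_kr), replace = TRUE)
  seqc <- paste(rbind("G", x, y), collapse = "")
  abbrev <- toupper(paste0(substr(species, 1, 3),
                           substr(sub(".* ", "", species), 1, 3)))
  chain_record(accession = paste(abbrev, chain_type, "SYN", sep = "_"),
               species = species, chain_type = chain_type,
               sequence = seqc)
}

# Save/restore .Random.seed so generators do not perturb the caller's
# RNG stream beyond their own set.seed discipline.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a synthetic collagen database
#'
#' One chain per (species, chain_type) over COL1A1, COL1A2, COL3A1.
#'
#' @param config a "sim_config".
#' @return a "collagen_db".
#' @export
generate_collagen_db <- function(config) {
  recs <- list()
  for (sp in config$species) {
    for (ct in CHAIN_TYPES) {
      recs[[paste(sp, ct)]] <- generate_chain(config, sp, ct)
    }
  }
  collagen_db(recs)
}

# Candidate truncation positions producing a nonspecific terminus.
# Returns list(c_ends, n_starts) for a pool peptide [s, e]; boundary
# membership supplied as a logical over 0..L.
truncation_options <- function(s, e, is_bound, min_len = 4L) {
  c_ends <- integer(0); n_starts <- integer(0)
  if (e - 1L >= s + min_len - 1L) {
    cand <- (s + min_len - 1L):(e - 1L)
    c_ends <- cand[!is_bound[cand + 1L]]
  }
  if (s + 1L <= e - min_len + 1L) {
    cand <- (s + 1L):(e - min_len + 1L)
    n_starts <- cand[!is_bound[cand]]
  }
  list(c_ends = c_ends, n_starts = n_starts)
}

#' Generate a synthetic PSM table with its truth ledger
#'
#' Peptides are sampled uniformly (with replacement) from the tryptic
#' digest of the database. With per-sample probability
#' `semitryptic_prob` one terminus is truncated to a uniformly chosen
#' internal, non-tryptic position (the kept specific terminus chosen
#' uniformly between the N and C side), so the emitted PSM is exactly
#' semitryptic; otherwise it is exactly fully tryptic. Deamidation is
#' drawn per N/Q site, oxidation per M site; intensities are
#' log-normal; ion scores are normal, clipped at zero.
#'
#' @param config a "sim_config".
#' @param db database built from [generate_collagen_db()] (or any
#'   "collagen_db" whose accessions the PSMs should cite).
#' @return list(psms, ledger): `psms` in the standard PSM-table layout,
#'   `ledger` a list with the generating parameters and realized
#'   per-sample draw totals.
#' @export
generate_psm_table <- function(config, db) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed((config$seed * 31L + 7L) %% 2147483L)

  db_df <- as.data.frame(db)
  # pool: observable tryptic peptides (length 6-45)
  pool <- do.call(rbind, lapply(seq_len(nrow(db_df)), function(i) {
    d <- digest(db_df[i, ], max_missed = config$max_missed,
                mode = "tryptic")
    d <- d[nchar(d$sequence) >= 6L & nchar(d$sequence) <= 45L, ,
           drop = FALSE]
    d
  }))
  check_that(nrow(pool) > 0L, "digest produced no observable peptides")
  chain_seq <- stats::setNames(db_df$sequence, db_df$accession)
  bound_by_acc <- lapply(chain_seq, function(sq) {
    L <- nchar(sq)
    b <- logical(L + 1L)
    b[c(0L, cleavage_sites(sq), L) + 1L] <- TRUE
    b
  })
  # which pool peptides admit a semitryptic truncation
  opts <- lapply(seq_len(nrow(pool)), function(i) {
    truncation_options(pool$start[i], pool$end[i],
                       bound_by_acc[[pool$accession[i]]])
  })
  truncatable <- vapply(opts, function(o) {
    length(o$c_ends) + length(o$n_starts) > 0L
  }, logical(1))
  if (!any(truncatable) && config$semitryptic_prob > 0) {
    stop("no pool peptide admits a semitryptic truncation", call. = FALSE)
  }

  all_psms <- list(); ledger_rows <- list()
  for (r in seq_len(nrow(config$samples))) {
    sid <- config$samples$sample_id[r]
    n <- as.integer(sample_param(config, r, "n_psms"))
    q <- sample_param(config, r, "semitryptic_prob")
    rate_n <- sample_param(config, r, "deamidation_rate_n")
    rate_q <- sample_param(config, r, "deamidation_rate_q")
    rate_ox <- sample_param(config, r, "oxidation_rate")
    if (q > 0 && q * n < 1) {
      warning(sprintf(
        "sample %s: semitryptic_prob * n_psms = %.2f < 1; recovery of q will be unreliable",
        sid, q * n))
    }
    resample <- function(x, k) x[sample.int(length(x), k, replace = TRUE)]
    semi <- stats::runif(n) < q
    idx <- integer(n)
    idx[!semi] <- resample(seq_len(nrow(pool)), sum(!semi))
    idx[semi] <- resample(which(truncatable), sum(semi))

    peptide <- pool$sequence[idx]
    start <- pool$start[idx]
    accession <- pool$accession[idx]
    for (i in which(semi)) {
      o <- opts[[idx[i]]]
      sides <- c(if (length(o$c_ends)) "C", if (length(o$n_starts)) "N")
      side <- if (length(sides) == 1L) sides else sample(sides, 1L)
      s0 <- pool$start[idx[i]]; e0 <- pool$end[idx[i]]
      if (side == "C") {
        e1 <- o$c_ends[sample.int(length(o$c_ends), 1L)]
        peptide[i] <- substr(chain_seq[[accession[i]]], s0, e1)
      } else {
        s1 <- o$n_starts[sample.int(length(o$n_starts), 1L)]
        peptide[i] <- substr(chain_seq[[accession[i]]], s1, e0)
        start[i] <- s1
      }
    }

    # per-site modification draws, vectorized over a long site table
    site_positions <- function(res) {
      g <- gregexpr(res, peptide, fixed = TRUE)
      lapply(g, function(p) if (p[1] == -1L) integer(0) else as.integer(p))
    }
    mods <- rep("", n)
    tallies <- list(N = c(0L, 0L), Q = c(0L, 0L), M = c(0L, 0L))
    for (res in c("N", "Q", "M")) {
      posl <- site_positions(res)
      cnt <- lengths(posl)
      if (sum(cnt) == 0L) next
      psm_of_site <- rep(seq_len(n), cnt)
      pos <- unlist(posl)
      rate <- switch(res, N = rate_n, Q = rate_q, M = rate_ox)
      hit <- stats::runif(length(pos)) < rate
      tallies[[res]] <- c(sum(cnt), sum(hit))
      if (any(hit)) {
        kind <- if (res == "M") "oxidation" else "deamidation"
        tok <- sprintf("%s@%d", kind, pos[hit])
        add <- vapply(split(tok, psm_of_site[hit]), paste,
                      character(1), collapse = ";")
        tgt <- as.integer(names(add))
        mods[tgt] <- ifelse(nzchar(mods[tgt]),
                            paste(mods[tgt], add, sep = ";"), add)
      }
    }

    intensity <- stats::rlnorm(n, config$intensity_meanlog,
                               config$intensity_sdlog)
    score <- pmax(0, stats::rnorm(n, config$score_mean, config$score_sd))

    decoy <- stats::runif(n) < config$unassignable_fraction
    for (i in which(decoy)) {
      ch <- sample(strsplit(peptide[i], "")[[1]])
      peptide[i] <- paste(rev(ch), collapse = "")
      mods[i] <- ""   # decoys model unassignable spectra, not bad mods
    }

    all_psms[[sid]] <- data.frame(
      sample_id = sid,
      spectrum_id = sprintf("%s_scan%06d", sid, seq_len(n)),
      peptide = peptide, modifications = mods,
      charge = sample(2:3, n, replace = TRUE),
      ion_score = round(score, 2),
      intensity = round(intensity, 1),
      accession = accession, start = start,
      stringsAsFactors = FALSE)
    ledger_rows[[sid]] <- data.frame(
      sample_id = sid, n_psms = n, semitryptic_prob = q,
      deamidation_rate_n = rate_n, deamidation_rate_q = rate_q,
      oxidation_rate = rate_ox,
      n_semitryptic_true = sum(semi), n_decoy = sum(decoy),
      n_sites_N = tallies$N[1], n_deam_N = tallies$N[2],
      n_sites_Q = tallies$Q[1], n_deam_Q = tallies$Q[2],
      n_sites_M = tallies$M[1], n_ox_M = tallies$M[2],
      stringsAsFactors = FALSE)
  }
  psms <- do.call(rbind, all_psms)
  rownames(psms) <- NULL
  ledger <- list(seed = config$seed,
                 samples = do.call(rbind, c(ledger_rows,
                                            make.row.names = FALSE)))
  list(psms = psms, ledger = ledger)
}
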