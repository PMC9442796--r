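# End-to-end orchestration: validate inputs, classify each sample,
# quantify deamidation and backbone cleavage, attach composition and
# DKP summaries when provided, and emit per-sample reports.
#
# The pipeline is a pure function of (inputs, config): repeated runs
# produce byte-identical reports. Every number in a report is computed
# by one of the stage functions; the report layer only formats.

#' Run the glue characterization pipeline
#'
#' @param config list (or path to a JSON file) with elements:
#'   \describe{
#'     \item{db_fasta}{path to the collagen FASTA database (required)}
#'     \item{psm_table}{path to the PSM TSV (required)}
#'     \item{aa_table}{optional amino-acid quantitation TSV}
#'     \item{dkp_table}{optional DKP peak-area TSV}
#'     \item{output_dir}{optional directory for report files}
#'     \item{score_threshold}{identification ion-score filter,
#'       exclusive (default 40)}
#'     \item{cleavage_cutoff}{cleavage-survey ion-score filter,
#'       inclusive (default 25)}
#'     \item{fish_taxa}{species treated as fish (default
#'       [default_fish_taxa()])}
#'     \item{seed}{optional; recorded in provenance only}
#'   }
#' @return invisibly, a named list of per-sample reports (lists); see
#'   the vignette for the layout.
#' @export
run_glue_pipeline <- function(config) {
  if (is.character(config)) {
    check_that(file.exists(config), "config file not found: %s", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  for (field in c("db_fasta", "psm_table")) {
    check_that(!is.null(config[[field]]),
               "config must name '%s'", field)
    check_that(file.exists(config[[field]]),
               "%s not found: %s", field, config[[field]])
  }
  score_threshold <- config$score_threshold %||% 40
  cleavage_cutoff <- config$cleavage_cutoff %||% 25
  fish_taxa <- config$fish_taxa %||% default_fish_taxa()

  db <- read_collagen_fasta(config$db_fasta)
  index <- build_peptide_index(db)
  psm_in <- read_psm_table(config$psm_table, db)
  message(sprintf("pipeline: %d PSM rows read, %d accepted, %d rejected",
                  psm_in$n_input, nrow(psm_in$psms),
                  nrow(psm_in$rejected)))
  psms <- psm_in$psms
  if (nrow(psms) == 0L) {
    warning("no accepted PSMs; any samples present will be unclassified")
  }

  aa <- if (!is.null(config$aa_table)) read_aa_table(config$aa_table)
  dkp <- if (!is.null(config$dkp_table)) read_dkp_table(config$dkp_table)

  samples <- sort(unique(c(psms$sample_id,
                           if (!is.null(aa)) aa$sample_id,
                           if (!is.null(dkp)) dkp$sample_id)))
  evidence <- infer_chains(psms, index, score_threshold = score_threshold)
  deam_chain <- summarize_deamidation(psms, index, scope = "chain")
  deam_global <- summarize_deamidation(psms, index, scope = "global")
  cleave_chain <- cleavage_index(psms, db, score_cutoff = cleavage_cutoff,
                                 scope = "chain")
  cleave_sample <- cleavage_index(psms, db, score_cutoff = cleavage_cutoff,
                                  scope = "sample")

  # hash the analytic configuration only: where outputs land must not
  # change what the reports say
  config_digest <- local({
    analytic <- config[setdiff(sort(names(config)), "output_dir")]
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    jsonlite::write_json(analytic, tmp, auto_unbox = TRUE, digits = NA)
    unname(tools::md5sum(tmp))
  })

  reports <- list()
  for (sid in samples) {
    ev <- evidence[evidence$sample_id == sid, , drop = FALSE]
    if (nrow(ev) == 0L) {
      ev <- data.frame(sample_id = character(0), species = character(0),
                       chain_type = character(0), accepted = logical(0))
    }
    cls <- classify_glue(ev, fish_taxa = fish_taxa)
    cls$sample_id <- sid
    if (cls$tissue == "unclassified") {
      warning(sprintf("sample %s: no accepted chains; unclassified", sid))
    }
    site_maps <- NULL
    accs <- unique(psms$accession[psms$sample_id == sid])
    if (length(accs)) {
      site_maps <- do.call(rbind, lapply(accs, function(a) {
        site_state_map(psms[psms$sample_id == sid, , drop = FALSE],
                       db[db$accession == a, ])
      }))
    }
    comp <- NULL
    if (!is.null(aa) && sid %in% aa$sample_id) {
      prof <- relative_composition(aa[aa$sample_id == sid,
                                      AA_PANEL, drop = FALSE])
      comp <- list(profile = as.list(round(prof, 4)),
                   polar_percent = round(polar_fraction(prof), 4))
    }
    dkps <- NULL
    if (!is.null(dkp) && sid %in% dkp$sample_id) {
      d <- dkp[dkp$sample_id == sid, , drop = FALSE]
      s <- dkp_summarize(stats::setNames(d$area, d$compound),
                         d$weight_mg[1])
      dkps <- list(total_normalized_area = s$total_normalized_area,
                   cyclo_pro_hyp_area = s$cyclo_pro_hyp_area)
    }
    reports[[sid]] <- list(
      sample_id = sid,
      classification = as.list(cls),
      chain_evidence = ev,
      deamidation = list(
        global = deam_global[deam_global$sample_id == sid, , drop = FALSE],
        per_chain = deam_chain[deam_chain$sample_id == sid, , drop = FALSE]),
      cleavage = list(
        sample = cleave_sample[cleave_sample$sample_id == sid, ,
                               drop = FALSE],
        per_chain = cleave_chain[cleave_chain$sample_id == sid, ,
                                 drop = FALSE]),
      site_maps = site_maps,
      composition = comp,
      dkp = dkps,
      provenance = list(config_md5 = config_digest,
                        db_fasta = config$db_fasta,
                        psm_table = config$psm_table,
                        seed = config$seed %||% NA,
                        n_psms_accepted = sum(psms$sample_id == sid),
                        n_psms_rejected = sum(
                          psm_in$rejected$sample_id == sid)))
  }

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (sid in names(reports)) {
      jsonlite::write_json(
        reports[[sid]],
        file.path(config$output_dir, paste0(sid, "_report.json")),
        auto_unbox = TRUE, digits = 10, dataframe = "rows", na = "null",
        pretty = TRUE)
    }
    utils::write.table(render_summary(reports),
                       file.path(config$output_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
  }
  invisible(reports)
}

#' Cross-sample summary table
#'
#' One row per sample: tissue and purity call, global mean glutamine
#' deamidation (percent), and the sample-level semitryptic cleavage
#' fraction — the table needed to compare cohorts (e.g. bone vs. hide).
#'
#' @param reports list of reports from [run_glue_pipeline()].
#' @return data.frame with columns sample_id, tissue, purity, label,
#'   n_species, species, mean_q_deamidation_pct, cleavage_fraction.
#' @export
render_summary <- function(reports) {
  check_that(length(reports) >= 1L, "need at least one report")
  out <- do.call(rbind, lapply(reports, function(r) {
    g <- r$deamidation$global
    gq <- g[g$residue_class == "Q", , drop = FALSE]
    cs <- r$cleavage$sample
    data.frame(sample_id = r$sample_id,
               tissue = r$classification$tissue,
               purity = r$classification$purity %||% NA_character_,
               label = r$classification$label %||% NA_character_,
               n_species = r$classification$n_species,
               species = r$classification$species,
               mean_q_deamidation_pct = if (nrow(gq)) gq$mean_fraction[1]
                 else NA_real_,
               cleavage_fraction = if (!is.null(cs) && nrow(cs))
                 cs$fraction[1] else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
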