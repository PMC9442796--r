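# Bulk amino-acid composition (GC-MS side) and diketopiperazine (DKP)
# pyrolysis summaries.
#
# The quantified amino-acid panel is the 13 residues recoverable after
# acid hydrolysis and silylation: Ala, Gly, Val, Leu, Ile, Met, Ser,
# Pro, Phe, Asp, Glu, Hyp, Tyr (Hyp = hydroxyproline, the collagen
# hallmark). Profiles are relative percentages over this panel.

AA_PANEL <- c("Ala", "Gly", "Val", "Leu", "Ile", "Met", "Ser", "Pro",
              "Phe", "Asp", "Glu", "Hyp", "Tyr")
POLAR_AAS <- c("Pro", "Hyp", "Asp", "Glu", "Ser")

#' Relative amino-acid composition
#'
#' @param amounts named numeric vector (or one-row data.frame) of
#'   nonnegative amounts for the 13-residue panel; any unit, since only
#'   ratios matter.
#' @return named numeric vector of percentages summing to 100.
#' @export
relative_composition <- function(amounts) {
  if (is.data.frame(amounts)) amounts <- unlist(amounts[1, , drop = TRUE])
  missing <- setdiff(AA_PANEL, names(amounts))
  check_that(length(missing) == 0L, "missing amino acid(s): %s",
             paste(missing, collapse = ", "))
  x <- as.numeric(amounts[AA_PANEL])
  names(x) <- AA_PANEL
  check_that(all(!is.na(x)) && all(x >= 0), "amounts must be nonnegative")
  total <- sum(x)
  check_that(total > 0, "all-zero amino-acid amounts")
  100 * x / total
}

#' Average amino-acid profile with confidence intervals
#'
#' Per amino acid: the mean over samples and a two-sided confidence
#' half-width t(1 - alpha/2, n - 1) * sd / sqrt(n). The t distribution
#' is used (rather than the normal) because sample sizes are small;
#' the choice is recorded in the `ci_method` attribute.
#'
#' @param profiles data.frame or matrix, one row per sample, columns
#'   the 13-residue panel (percent).
#' @param alpha two-sided significance level (default 0.05).
#' @return data.frame: amino_acid, mean_percent, ci_half_width.
#' @export
average_profile <- function(profiles, alpha = 0.05) {
  profiles <- as.data.frame(profiles)
  missing <- setdiff(AA_PANEL, names(profiles))
  check_that(length(missing) == 0L, "missing amino acid(s): %s",
             paste(missing, collapse = ", "))
  n <- nrow(profiles)
  check_that(n >= 2L, "need at least 2 profiles, got %d", n)
  tcrit <- stats::qt(1 - alpha / 2, df = n - 1)
  out <- data.frame(
    amino_acid = AA_PANEL,
    mean_percent = vapply(AA_PANEL, function(a) mean(profiles[[a]]), numeric(1)),
    ci_half_width = vapply(AA_PANEL, function(a) {
      tcrit * stats::sd(profiles[[a]]) / sqrt(n)
    }, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "ci_method") <- sprintf("t, alpha = %g, df = %d", alpha, n - 1)
  out
}

#' Polar amino-acid fraction of a profile
#'
#' Sum of the polar residues Pro, Hyp, Asp, Glu and Ser. Mammalian
#' collagens sit around 50-55 percent; marine collagens run lower.
#'
#' @param profile named percentage vector as from
#'   [relative_composition()].
#' @return the polar percentage.
#' @export
polar_fraction <- function(profile) {
  if (is.data.frame(profile)) profile <- unlist(profile[1, , drop = TRUE])
  missing <- setdiff(POLAR_AAS, names(profile))
  check_that(length(missing) == 0L, "missing amino acid(s): %s",
             paste(missing, collapse = ", "))
  sum(as.numeric(profile[POLAR_AAS]))
}

#' Summarize DKP pyrolysis peak areas
#'
#' Normalizes every diketopiperazine peak area by the sample weight and
#' totals them; total DKP yield proxies chain depolymerization, and the
#' collagen-diagnostic Cyclo(Pro-Hyp) area is reported separately for
#' the total-vs-Cyclo(Pro-Hyp) scatter.
#'
#' @param areas named numeric vector of peak areas per DKP compound
#'   (may be empty).
#' @param sample_weight sample weight (> 0), same unit for all samples.
#' @param cyclo_pro_hyp name of the Cyclo(Pro-Hyp) compound in `areas`.
#' @return list: normalized (named vector), total_normalized_area,
#'   cyclo_pro_hyp_area (0 when absent).
#' @export
dkp_summarize <- function(areas, sample_weight,
                          cyclo_pro_hyp = "Cyclo(Pro-Hyp)") {
  check_that(is.numeric(sample_weight) && length(sample_weight) == 1L &&
               sample_weight > 0, "sample_weight must be > 0")
  check_that(all(areas >= 0), "areas must be nonnegative")
  normalized <- areas / sample_weight
  list(normalized = normalized,
       total_normalized_area = sum(normalized),
       cyclo_pro_hyp_area = if (cyclo_pro_hyp %in% names(normalized))
         unname(normalized[cyclo_pro_hyp]) else 0)
}

#' Read an amino-acid quantitation table
#'
#' @param path TSV with a `sample_id` column plus the 13-residue panel.
#' @return data.frame as read.
#' @export
read_aa_table <- function(path) {
  check_that(file.exists(path), "file not found: %s", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(c("sample_id", AA_PANEL), names(tab))
  check_that(length(missing) == 0L, "missing column(s): %s",
             paste(missing, collapse = ", "))
  tab
}

#' Read a DKP peak-area table
#'
#' @param path TSV with columns sample_id, compound, area, weight_mg.
#' @return data.frame as read.
#' @export
read_dkp_table <- function(path) {
  check_that(file.exists(path), "file not found: %s", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(c("sample_id", "compound", "area", "weight_mg"),
                     names(tab))
  check_that(length(missing) == 0L, "missing column(s): %s",
             paste(missing, collapse = ", "))
  tab
}
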