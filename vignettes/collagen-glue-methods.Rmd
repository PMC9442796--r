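---
title: "Methods: characterizing collagen-based animal glues from PSM evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing collagen-based animal glues from PSM evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collaglue)
```

## The problem

Animal glues are gelatinized collagen. Three questions matter to a
conservator choosing or analyzing one: which tissue it came from (hide
vs. bone vs. fish), whether it is a single-species or blended product,
and how degraded the protein is. All three are answerable from standard
shotgun-proteomics evidence — peptide-spectrum matches (PSMs) against a
small, curated database of collagen chain sequences — plus two bulk
measurements (amino-acid composition by GC-MS and diketopiperazine
yields by pyrolysis-GC-MS). This package implements that analysis as a
reusable, tested pipeline. Spectral searching itself (Mascot, MaxQuant),
decoy-based FDR estimation and instrument processing are upstream and
out of scope: the inputs are already-assigned PSM tables.

## Reference database and digestion

The database holds one entry per (species, chain) for the fibrillar
chains COL1A1, COL1A2 and COL3A1, in FASTA with
`>accession|species|chain_type` headers. Coordinates are 1-based on the
database entry exactly as supplied; no signal-peptide trimming is
applied, so site positions always refer to database numbering. Whether
entries are mature chains or full precursors is the curator's choice —
the package takes the sequence at face value. Hydroxyproline is not
encoded in sequences; hydroxylation, like oxidation and deamidation, is
a PSM-level modification.

In-silico digestion uses the Mascot-style trypsin dialect: cleavage
C-terminal to K or R, blocked when the next residue is proline (the
block can be disabled), protein termini always counting as specific.
Tryptic mode emits every fully specific peptide with at most
`max_missed` (default 3) internal sites; semitryptic mode additionally
emits every peptide with exactly one specific terminus. The
implementation builds peptides from boundary pairs; its correctness is
established against an independent oracle that enumerates *all*
substrings and filters them by the specificity predicate — the two must
agree exactly on random sequences in both modes.

The peptide index collapses isoleucine and leucine (isobaric,
indistinguishable in this workflow) to a single symbol for lookup and
uniqueness reasoning only; stored sequences are never mutated.

## Species inference and glue classification

A chain is accepted for a sample when at least **2 different
non-overlapping peptides** have ion score strictly above 40
("above the threshold" is read as exclusive). Non-overlapping means
positionally disjoint intervals on the chain. Because a peptide can
occur at several positions in a repetitive collagen sequence, the
maximum-disjoint count with a "count each peptide once" constraint is a
job-interval-selection problem (NP-hard in general, and a greedy with a
used-key skip is demonstrably suboptimal). We therefore reduce first:
each distinct peptide contributes exactly one interval, its earliest
occurrence; earliest-end greedy scheduling is then provably optimal.
The reduction is conservative — a repeated peptide can never count as
two pieces of evidence.

Tissue and purity rules:

* any accepted fish species → **fish-mixed** (a fish glue lacking
  COL3A1 is not a bone glue; fish taxa are configurable, default
  `default_fish_taxa()`);
* otherwise COL3A1 accepted for ≥ 1 species → **hide**;
* otherwise → **bone**;
* no accepted chain at all → **unclassified** (a distinct outcome,
  never an error);
* **pure** iff exactly one accepted species. A species is reported
  only via accepted chains — isolated shared-peptide hits never create
  a species, because species discrimination in collagen rests on very
  few unique peptides.

`classify_from_matrix()` applies the same rules to a transcribed
detection matrix (flags taken at face value, as published
identification tables apply their filters per chain or per species
inconsistently); `infer_chains()` applies the 2-peptide filter per
chain.

## Deamidation

Deamidation converts the Asn/Gln side-chain amide to a carboxylate
(+0.98402 Da, computed in `mod_mass_delta()` from monoisotopic atomic
masses). Conventions, chosen once and applied throughout:

* **PSM occupancy** = deamidation events of a residue class / number
  of residues of that class in the peptide. An unlocalized event
  (`deamidation@?`) is attributed only when every candidate N/Q in the
  peptide belongs to one class; otherwise it is ambiguous and excluded.
* **Peptide fraction** = intensity-weighted mean of PSM occupancies.
  When any contributing intensity is missing the weights fall back to
  plain PSM counting, recorded in `weight_basis` — counting is the only
  option when intensities are absent.
* **Summaries** (per chain, per protein family pooling homologous
  chain types across species, or global) are *unweighted* means across
  peptide fractions, in percent, with SD and the number of peptides;
  intensity weighting happens only within a peptide. A peptide shared
  by several chains inside one scope group is counted once in that
  group, preventing double counting under family pooling.
* N and Q are always reported separately and never merged: Asn
  deamidation is much faster and therefore usually less informative
  than Gln deamidation.
* The global scope pools all peptides directly rather than weighting
  chains by abundance (the simplest declared choice).

## Backbone cleavage and site maps

Gelatinization hydrolyzes the backbone; upon tryptic digestion this
yields peptides with a trypsin-conforming terminus at exactly one end.
The cleavage index is semitryptic PSMs over tryptic-plus-semitryptic
PSMs per scope, counting PSMs (not unique peptides). The ion-score
cutoff here is **≥ 25 inclusive**, deliberately different from the
exclusive > 40 identification filter — the two filters model different
wordings of the respective survey settings. PSMs with *no* specific
terminus cannot arise from a semitryptic search; they are excluded from
both numerator and denominator and reported separately as diagnostics.

Site maps label every N, Q and M of a chain: D / DX / X / NF for
deamidation, OX / X / NF for oxidation. A methionine observed both
oxidized and unmodified has no label in the three-way scheme, so the
package adds an explicit composite state **OXX** rather than silently
mapping it onto OX. Ambiguous (unlocalized, multi-candidate) PSMs are
excluded from state calls; a position covered only by ambiguous
evidence reports NF.

## Bulk composition

`relative_composition()` normalizes the 13-residue GC-MS panel (Ala,
Gly, Val, Leu, Ile, Met, Ser, Pro, Phe, Asp, Glu, Hyp, Tyr) to percent.
`average_profile()` reports means with two-sided half-widths
`t(1 − α/2, n − 1) · sd / √n`; the t distribution is used rather than
the normal because cohort sizes are small (the choice is recorded in
the output's `ci_method` attribute). The polar fraction sums Pro, Hyp,
Asp, Glu, Ser — mammalian collagens sit near 50–55 %, marine collagens
lower. DKP pyrolysis areas are normalized by sample weight; the total
proxies depolymerization, and Cyclo(Pro-Hyp) — the collagen-diagnostic
DKP — is reported separately for the total-vs-Cyclo(Pro-Hyp) scatter.
GC-MS calibration and recovery are upstream chemistry; inputs are
already-quantified amounts.

## The synthetic-data generator

Real raw data cannot ship with a package; the generator stands in for
it with known ground truth. It emulates:

* **chains**: Gly-X-Y triplets (G at every first position, so glycine
  is exactly one third), Pro-enriched X, Pro/Ala-enriched Y, K/R
  inserted at Y positions at rate 0.22 (a tryptic site roughly every
  4–5 triplets, giving realistic peptide lengths), N/Q/M placed at
  rates that guarantee sites for every estimator; default chain length
  501 residues, a compromise between realism and test runtime;
* **PSMs**: peptides sampled uniformly from the tryptic digest
  (observable lengths 6–45); with probability `semitryptic_prob` one
  terminus is truncated to a uniformly chosen internal *non-tryptic*
  position (kept side chosen uniformly), so the emitted PSM is exactly
  semitryptic when drawn and exactly fully tryptic otherwise — the
  boundary configurations q = 0 and q = 1 yield index 0 and 1 exactly;
* **modifications**: per-site Bernoulli draws (defaults: N 0.5, Q 0.35,
  M oxidation 0.8 — mid-range hide-glue-like deamidation and the
  observation that detected methionines are almost always oxidized);
* **intensities** log-normal (meanlog 14, sdlog 1) and **ion scores**
  normal (mean 45, sd 18, clipped at 0), deliberately straddling both
  the 25 and 40 thresholds so the filters always bite.

Every draw lands in a truth ledger (per-sample site and truncation
totals), sufficient to compute expected estimator values in closed
form. Outputs are bit-identical for identical seeds. The generator does
*not* simulate retention times, m/z, spectral noise, search-engine
score calibration, sequence-context deamidation kinetics, or
correlated modification hot-spots — so passing recovery tests show the
estimators are correct *given* correctly assigned PSMs, not that any
search engine assigns them correctly.

## Validation design and numerical choices

The test suite checks, among others: digestion against brute-force
substring enumeration; the greedy evidence count against brute-force
maximum-independent-set; deamidation and cleavage parameter recovery
on simulated samples; site-map totality (every N/Q/M receives a state)
with exact behaviour at rate 0 and 1; and composition arithmetic
against closed-form t expressions. Recovery experiments use chains of
501 residues, 200–1000 PSMs per sample and up to 100 replicates per
condition — sizes chosen so the whole battery runs on a laptop in a
few minutes.

One statistical caveat is worth stating plainly. A "within 2 SE"
recovery check has ~95 % nominal coverage, so demanding it hold in
≥ 95 % of replicates sits exactly at the attainable boundary; at
extreme rates (e.g. 0.05) with shallow sampling the peptide-fraction
distribution is highly skewed and 2-SE intervals genuinely
under-cover. The acceptance battery reports this coverage as measured;
unit tests use single-run 3-SE smoke bounds instead, which is the
appropriate strictness for a deterministic fixed-seed check.

Other numerical conventions: ties in `compare_scopes()` break on scope
labels for determinism; empty scopes are omitted rather than reported
as NaN; all tabular outputs are plain TSV and reports JSON, written
with fixed formatting so repeated pipeline runs are byte-identical
(the provenance hash covers the analytic configuration only, not
output paths).

## Limitations

* Classification quality is bounded by the curated database: a species
  missing from it can only surface as shared-peptide evidence for a
  relative, never as itself.
* The 2-peptides-above-40 filter is a manual-curation surrogate, not a
  decoy-FDR procedure.
* Family pooling treats homologous chains as exchangeable; strongly
  divergent fish chains make family summaries harder to interpret.
* Bulk composition and DKP summaries are format-faithful re-analyses
  of upstream quantitation; the package does not model the chemistry
  that produced those numbers.
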