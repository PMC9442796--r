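Package: collaglue
Title: Proteomic Characterization of Collagen-Based Animal Glues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize collagen-based animal glues from
    peptide-spectrum-match (PSM) tables searched against a collagen
    reference database. Classifies glues by tissue source (hide, bone,
    fish) using collagen alpha-1(III) as a skin/connective-tissue marker
    and by purity (single vs. multiple source species), and quantifies
    degradation: asparagine/glutamine deamidation at peptide, chain,
    family and sample level; backbone cleavage via the semitryptic PSM
    fraction; site-specific deamidation and methionine-oxidation state
    maps; bulk amino-acid composition with confidence intervals; and
    diketopiperazine (DKP) pyrolysis summaries. Includes in-silico
    tryptic and semitryptic digestion, a peptide-to-chain index with
    isoleucine/leucine equivalence, and a synthetic-data generator that
    produces collagen-like Gly-X-Y chains and PSM tables with known
    ground truth so every estimator can be validated without raw
    mass-spectrometry data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
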