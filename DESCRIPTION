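Package: mitonuclear
Title: Mitonuclear Expression Coordination Analysis for Cloned Piglets
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for studying coordination between nuclear- and
    mitochondrially-encoded gene expression in somatic-cell nuclear transfer
    (SCNT) piglets and controls. Implements maternal-lineage assignment from an
    ND1 single-nucleotide polymorphism panel (with heteroplasmy detection and
    variant-effect classification under the vertebrate mitochondrial code),
    two-channel cDNA microarray processing (background subtraction, present
    calls, per-slide Lowess normalization, dye-swap combination and
    informative-probe filtering), genome-of-origin partitioned hierarchical
    clustering with treatment-coherence statistics, Welch-t /
    Benjamini-Hochberg differential expression with Fisher exact gene-set
    enrichment, and comparative-CT qPCR quantification with microarray
    concordance reporting. A deterministic synthetic-data generator emulates
    the full study design so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
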