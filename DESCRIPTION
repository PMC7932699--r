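Package: finlimbglass
Title: Cross-Species Comparison of Fin and Limb Developmental Programs
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing developmental gene-expression and
    open-chromatin time courses between distantly related vertebrates,
    modelled on a paired fin-bud / limb-bud study design. Implements
    cross-species best-hit ortholog assignment over a multi-species
    homology panel with a fallback lineage, four expression scaling
    methods (Max-1, z-score, unit-vector, log10), cross-species
    stage-distance matrices under four metrics for developmental
    hourglass analysis, heterochrony detection by stage correlation,
    Shannon-entropy tissue specificity, and ATAC-seq peak analytics
    (fixed-width genome binning, one-hot sample distances, alignment
    based conservation fractions, FRiP, differential-bin counts, PWM
    motif occurrence counting, and tissue-specific peak detection).
    A synthetic-data module generates all inputs with planted ground
    truth so every stage of the pipeline is testable without external
    downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
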