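Package: nullorna
Title: Nullomer Emergence from Somatic Mutations and Liquid-Biopsy
    Classification from cfRNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Enumerates nullomers (k-mers absent from a genome on both
    strands), detects the nullomers that emerge when somatic mutations
    edit the reference sequence, classifies mutations into SBS96 and
    ID83 mutational channels, aggregates cohort-level statistics
    (per-patient burden, recurrence, cancer-type specificity, gene
    density, VAF stratification), screens cell-free RNA reads for a
    nullomer panel, and classifies cancer versus healthy samples with
    an L1-regularized logistic model under repeated stratified
    cross-validation, with Brier scoring, Platt recalibration and
    feature-stability selection. Includes generators for synthetic
    genomes, somatic-variant cohorts and spiked cfRNA read sets so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    edgeR,
    glmnet,
    jsonlite,
    pROC,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
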