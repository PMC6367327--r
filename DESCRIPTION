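Package: varlevel
Title: Multi-Level Pathogenicity Analysis of Non-Synonymous SNVs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the pathogenicity of non-synonymous
    single-nucleotide variants at several levels of biological organization:
    per-tool and all-agree ensemble evaluation of twelve rank-score
    pathogenicity predictors, conservation-stratified enrichment of
    prediction errors, four-allele score statistics (maximum and coefficient
    of variation) at non-degenerate sites, gene-level disease-susceptibility
    classes with expression abundance, tissue-specificity and
    protein-interaction degree comparisons, and chromatin-state (repressed
    PolyComb) overlap of variant sites across epigenomes. Ships a seeded
    synthetic cohort generator with configurable planted effects so every
    analysis stage can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    rtracklayer
Config/testthat/edition: 3
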