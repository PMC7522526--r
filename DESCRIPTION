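Package: methlink
Title: Linking Bacterial SMRT Methylomes to Transcript and Protein Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrative analysis of bacterial DNA methylomes called from
    single-molecule sequencing kinetics (interpulse-duration ratios) together
    with transcript and protein differential expression. Provides IUPAC-aware
    scanning for degenerate bipartite restriction-modification motifs on
    circular genomes, m6A/m4C modification calling under coverage and
    IPD-ratio thresholds, assignment of methylated sites to gene bodies and
    500-bp upstream windows, Welch t-test and Benjamini-Hochberg based
    differential-expression statistics for microarray and label-free
    proteome intensity tables, three-tier methylation/transcript/protein
    co-occurrence summaries, nearest-neighbor duplex-stability profiling
    over genome windows, and NG86-style Ka/Ks estimation with pair filters
    for purifying-selection screens. A seeded synthetic-data module
    generates every input format with planted ground truth for recovery
    testing, and a pipeline orchestrator runs all stages end to end.
License: MIT
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
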