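Package: musselnet
Title: Tissue-Specific Co-Expression Network Inference for Two-Channel
    cDNA Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers gene co-expression networks from tissue-specific
    two-channel cDNA microarray data, following the classic pipeline used
    for the Mytilus galloprovincialis MyArray 1.0 tissue atlas (GEO
    accession GSE2176): log2 ratio normalization, per-gene one-way ANOVA
    across tissues, all-pairs Pearson correlation thresholding, Markov
    Clustering (MCL) of the resulting network, and extraction of
    seed-gene (e.g. heat shock protein) neighborhoods with summary
    network statistics.  Also provides position-weight-matrix scanning
    of promoter sequences and Smith-Waterman local alignment with
    percent identity, plus a synthetic-data generator with planted
    differential expression and planted co-expression modules so the
    whole pipeline is testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
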