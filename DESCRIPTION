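Package: degnet
Title: Case-Control Transcriptome Signatures, Interactome
    Over-Connectivity and Chromosomal Hot-Spot Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable analysis chain for case-control microarray blood
    transcriptome studies: coefficient-of-variation filtering with two-way
    hierarchical clustering and principal components analysis, per-probe
    Welch differential expression with fold-change thresholds and
    probe-to-gene collapsing, hypergeometric gene-set over-representation
    with Benjamini-Hochberg false discovery rates, hypergeometric
    over-connectivity z-scores of dataset-mapped objects against a curated
    protein interaction background (with over-connected pairs, topology
    summaries and hidden transcription-factor ranking), and a chromosomal
    hot-spot scan statistic for stretches of consecutive genes enriched in
    differentially expressed genes. Includes a synthetic-data generator
    that plants differential genes, network hubs, enriched terms and
    genomic hot spots with a known truth record so every stage is testable
    without access to raw arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    cluster,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
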