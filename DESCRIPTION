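Package: phenolnet
Title: Multilayer Regulatory Network Construction for Berry
    Phenylpropanoid Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds condition-specific signed gene co-expression networks
    from developmental RNA-Seq abundance tables (Pearson correlation
    thresholding), integrates them with lncRNA-gene genomic co-location
    edges, plant-style miRNA target predictions, and promoter
    cis-regulatory-element annotation and enrichment, and extracts
    pathway-focused regulatory subnetworks with module detection and
    degree-centrality reporting. Includes a synthetic-data generator that
    emulates a multi-cultivar, multi-stage berry ripening study design
    with planted co-expression modules, a tandem paralog cluster with
    adjacent and antisense lncRNAs, planted promoter motifs, and
    miRNA/target pairs of controlled complementarity, so the whole
    pipeline is testable without external genomic resources.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
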