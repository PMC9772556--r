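Package: glycolink
Title: Integrated Lectin-Microarray and Glycogene Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for integrating lectin-microarray glycan profiling with
    transcriptomics of glycan-related genes in two-group designs such as the
    valproic-acid (VPA) rat model of autism. Implements spot-level background
    filtering and median-ratio block normalization of lectin microarrays,
    signed fold-change calling, assembly and querying of a curated
    glycan-related gene list (CAZy/KEGG categories), identification of
    differentially expressed glycan-related genes (DEGGs) with
    Benjamini-Hochberg control, lectin-enzyme concordance scoring of glycan
    motifs, hypergeometric over-representation analysis, Markov clustering of
    confidence-weighted interaction networks, behavioural sociability
    statistics, and seeded synthetic-data generators with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    DESeq2,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
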