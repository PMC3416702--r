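Package: tissuespec
Title: Tissue-Specific Expression Calling from Multi-Tissue RNA-seq Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies genes specifically or preferentially expressed in one
    tissue from unreplicated multi-tissue RNA-seq read counts. Implements RPKM
    normalization with longest-transcript gene lengths, a counts-per-million
    presence filter, the Audic-Claverie exact test for digital gene expression
    between two sequencing libraries with Benjamini-Hochberg false discovery
    rate control, hypergeometric (singular) and PAGE z-score gene-set
    enrichment, best-hit filtering of tabular protein-alignment results with
    cross-species conservation partitioning, and Pearson/Spearman concordance
    analyses. Ships a synthetic-data generator with planted tissue-specific and
    tissue-preferential genes so that the whole pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    BiocGenerics,
    optparse
Config/testthat/edition: 3
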