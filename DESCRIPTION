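Package: platemux
Title: Four-Barcode Combinatorial Indexing for Scalable Colony Genotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing and analysing four-barcode combinatorially
    indexed amplicon libraries for high-throughput microbial colony genotyping.
    Builds barcoded primer layouts across well plates (rows encoded by interior
    forward indices, columns by interior reverse indices, plates by dual-unique
    exterior i5/i7-style indices), computes primer-count scaling for competing
    indexing schemes, simulates paired-end amplicon reads with substitution
    error and index hopping, demultiplexes reads back to wells with
    mismatch-tolerant barcode matching, derives representative amplicon
    sequence variants per well by read-count and proportion thresholds, and
    models per-colony workflow costs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
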