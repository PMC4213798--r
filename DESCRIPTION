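Package: mlclust
Title: Multi-Level Threshold Clustering of Biological Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Threshold-based clustering of DNA and protein sequences without
    computing a full pairwise-similarity matrix. Implements greedy clustering
    (GC), connected-component-based clustering (CCBC) and the multi-level
    algorithms MLC1, MLC and rMLC, which cluster blocks of sequences at
    increasing percent-identity thresholds and only compare group
    representatives across blocks. Includes exact accounting of pairwise
    alignments performed (the f-value cost metric), clustering F-measure
    evaluation against reference partitions, an optimal-threshold scan, and a
    synthetic sequence-family generator with planted ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
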