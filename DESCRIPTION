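Package: operonpolar
Title: Transcriptional and Post-Transcriptional Polar Effects in
    Bacterial Deletion Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies polar effects of single-gene deletions on the other
    members of bacterial operons. Computes median-reference log2 fold
    changes from multiplexed (TMT) protein signal-sum intensity matrices
    and from strand-separated WIG coverage tracks, assigns operon-relative
    gene positions, applies upstream/downstream median corrections,
    classifies operon-level transcriptional effects, and tests for the
    additional post-transcriptional downregulation of the gene directly
    downstream of a deletion, including its dependence on the intergenic
    distance to the deleted gene's stop codon. A synthetic mutant-library
    generator with known ground truth supports end-to-end validation of
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
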