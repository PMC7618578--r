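Package: mccutools
Title: Base-Pair-Resolution Micro-Capture-C Contact Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for base-pair-resolution chromosome conformation capture
    (Micro-Capture-C ultra) data: a ground-truthed simulator of MNase-based
    proximity-ligation sequencing libraries, paired-read overlap merging and
    sub-read splitting, precise ligation-junction calling with read
    directionality and PCR deduplication, 1-bp contact matrices with ICE and
    cis normalization, contact sequence reconstruction from junction
    directionality, block-level differential contact testing with
    zero-inflated negative binomial models (basepairC-style), viewpoint peak
    comparison, and capture oligonucleotide tiling design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Matrix,
    tools,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    mgcv
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    yaml,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
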