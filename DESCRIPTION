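Package: hicdesk
Title: Hi-C Contact Matrix Construction, Normalization and Structural Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds fragment-level Hi-C interaction matrices from separately
    aligned read-ends, annotates restriction fragments or fixed-size bins with
    genomic and epigenomic tracks, and provides higher-level analyses:
    distance/coverage, iterative (ICE) and Poisson-regression normalization,
    sample correlation via virtual 4C profiles, relative/correlated/signed
    difference matrices for sample comparison, interaction decay exponents,
    first-principal-component compartment calling with feature enrichment
    tests, and balanced-resampling tests for regions of interest. Includes a
    seed-deterministic synthetic data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
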