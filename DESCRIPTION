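Package: lohsym
Title: Reference-Symmetric Genotyping and Loss-of-Heterozygosity Inference
    for Mutation Accumulation Experiments
Version: 0.1.0
Authors@R:
    person("lohsym", "maintainers", email = "devnull@example.org",
           role = c("aut", "cre"))
Description: Detection and rate estimation of loss-of-heterozygosity (LOH)
    events from mutation accumulation experiments in heterozygous diploid
    hybrids. Implements dual-reference genotype reconciliation that is
    symmetric with respect to the two parental genomes, a founder
    genotyping-error model with posterior odds ratios for false homozygous
    and false heterozygous calls, a beta-binomial allele-balance filter for
    dubious heterozygous calls, interstitial and terminal LOH event
    detection with corrections for undetected events, P0-method rate
    estimation, binomial scans for high-conversion high-bias windows, and
    generalized linear mixed models with stitched link functions for
    partitioning LOH-rate variance into cis and trans components. A
    synthetic experiment simulator with full truth bookkeeping closes the
    testing loop without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    methods,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    VariantAnnotation
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
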