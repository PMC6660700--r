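Package: mosascan
Title: Mosaic SNV Calling and Cohort Characterization for Clinical Exome Data
Version: 0.1.0
Authors@R:
    person("mosascan", "developers", email = "mosascan@example.org",
           role = c("aut", "cre"))
Description: Detection and characterization of somatic mosaic single
    nucleotide variants from clinical exome read counts. Implements
    alternate-allele-fraction (AAF) thresholding for diploid and hemizygous
    loci with exact binomial confidence intervals, a depth-adaptive
    threshold mode, trio-based inheritance-origin assignment with a
    uniparental-disomy suspicion flag, cohort summary statistics over a
    bundled 120-record diagnostic cohort table, and read-count-level
    simulation of threshold operating characteristics and synthetic trio
    cohorts with planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    BiocGenerics,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
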