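Package: RegulaTE
Title: Regulatory Profiling of Transposable-Element Subfamilies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrated profiling of the regulatory activity of a repeat
    subfamily from transcription-factor binding intervals, epigenetic
    coverage and differential-transcript tables. Provides element-centred
    binding and RPKM meta-profiles, projection of binding sites and motif
    hits onto repeat consensus coordinates, pairwise TFBS co-localisation
    statistics with one-tailed two-proportion z-tests under Bonferroni
    control, PWM scanning with exact dynamic-programming p-value
    calibration, and a circular-rotation permutation test with a binomial
    tail for TSS-in-element enrichment. A seeded synthetic-fixture
    generator emulates every input format with known planted structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
biocViews: Epigenetics, Transcription, Coverage, MotifAnnotation,
    StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
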