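Package: riskogram
Title: Integrated Genetic and Clinical Wellness Risk Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns curated case-control association records and individual
    genotypes into per-disease post-test probabilities by sample-size-weighted
    genotype likelihood ratios, and integrates them with longitudinal clinical
    measurements. Provides catalog curation (significance filtering and
    haplotype-block pruning), Bayesian pre/post-test odds updating, cohort
    z-scoring with five-level risk binning, clinical conditioning of baseline
    risk (Framingham-ratio and heritability-scaled), risk-o-gram and gridiron
    assembly, concordance classification, and a fully synthetic cohort
    simulator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    igraph,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
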