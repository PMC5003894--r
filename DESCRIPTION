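Package: introscan
Title: Marker-Fingerprint Characterization of Introgression Lines
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of dominant molecular-marker fingerprints (SSR, AFLP,
    MSAP) for introgression lines derived from asymmetric somatic
    hybridization. Provides a validated presence/absence band-matrix
    container built on SummarizedExperiment, parental-origin classification
    of loci, per-line calling of introgression, loss, novel-band and
    reference-co-migrating events with informative-locus denominators,
    dual-digest (HpaII/MspI) methylation-state classification with
    hyper-/hypomethylation frequencies, a synthetic fingerprint generator
    with ground truth for parameter-recovery testing, and publication-style
    summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Epigenetics, Genetics, DataImport
RoxygenNote: 7.3.3
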