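Package: mirfill
Title: Small-RNA Annotation, Novel miRNA Discovery and Expression
    Dynamics of Rice Grain Filling
Version: 0.1.0
Authors@R:
    person("Grain-Filling", "Pipeline Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable re-implementation of a small-RNA analysis pipeline
    for the rice grain-filling stage series (10, 15, 21, 27 and 35 days
    after flowering): collapsing and annotating small-RNA reads by a strict
    priority rule, hairpin-based discovery of novel miRNAs with
    MIREAP-style duplex criteria, rule-based plant miRNA target prediction
    with G:U half-mismatch weighting and a 75 percent duplex-energy test,
    NlaIII/MmeI digital gene-expression tag quantification of target
    genes, and expression-dynamics analysis against a logistic
    grain-filling growth model.  A seeded synthetic-data generator
    emulates the study design so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
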