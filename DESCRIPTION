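Package: rbpatlas
Title: RNA-Binding Protein Site Atlases from PAR-iCLIP and mRNA Decay
    Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds functionally annotated binding-site atlases for
    AU-rich-element binding proteins (tristetraprolin, HuR) from
    PAR-iCLIP alignments and actinomycin-D RNA-seq time courses.
    Provides crosslink-event extraction with truncation/T-to-C
    diagnostics, randomization-based (modFDR-style) cluster calling
    with recursive summit splitting and replicate consensus, exon-first
    region annotation, expression-normalized binding scores, log-linear
    mRNA decay fits with genotype interaction tests, AU-rich element
    scanning with a built-in RNA accessibility partition function and
    ROC evaluation, overlap and correlation analytics, and a synthetic
    data generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    MASS,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
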