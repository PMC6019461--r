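Package: mafseq
Title: Molecular Amplification Fingerprinting for Antibody Repertoire
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for error- and bias-corrected antibody repertoire
    sequencing (Ig-seq) built around molecular amplification
    fingerprinting (MAF): design and validation of synthetic spike-in
    standard sets with guaranteed CDR3 separability, simulation of
    UID-tagged Ig-seq reads with per-primer amplification bias and
    PCR/sequencing errors, reverse-UID (RID) consensus error correction,
    FID:RID amplification-bias normalization, germline V/J annotation
    with CDR3 extraction and somatic hypermutation counting, clonotype
    clustering, spike-in based accuracy metrics, and incidence-based
    (Chao2) clonal diversity estimation across cellular replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
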