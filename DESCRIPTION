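Package: retrocall
Title: Somatic Retrotransposition Calling from Tumor/Normal Paired-End Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects somatic mobile element insertions (LINE-1, Alu, SVA,
    ERV-K and processed pseudogenes) from tumor/normal paired-end whole-genome
    alignments by discordant read-pair clustering, characterizes each insertion
    to base-pair resolution (breakpoints, target-site duplication, poly(A)
    tract, L1-endonuclease motif, 5' truncation), traces L1 3' transductions
    back to their germline or somatic source elements, and detects L1-mediated
    deletions by copy-number matching and a resampled read-depth-drop test with
    Benjamini-Hochberg tiering. Includes cohort-level statistics (zero-inflated
    negative binomial enrichment, endonuclease-motif feature binning with
    negative binomial regression, Mann-Whitney group tests, Spearman
    correlation) and a seeded synthetic-genome simulator with truth-registry
    scoring for precision/recall validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    VariantAnnotation,
    rtracklayer
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
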