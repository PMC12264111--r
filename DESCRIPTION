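Package: pivarkit
Title: Genetic Variation in piRNA Cluster Expression Across Mouse Strains
Version: 0.1.0
Authors@R:
    person("pivarkit", "developers", email = "pivarkit@example.org",
           role = c("aut", "cre"))
Description: A pipeline for quantifying genetic variation in piRNA-cluster
    expression across inbred mouse strains and outbred pedigrees: de novo
    cluster discovery from small-RNA alignments with density-based
    reallocation of multimapping reads, cross-strain coordinate conversion
    and same-strand union merging with repeat and count filters,
    negative-binomial differential expression with per-cluster strain
    variance decomposition and a global mixed model, pedigree-based
    heritability by spectral REML with a stratified permutation null,
    strand-aware association of polymorphic transposable elements with
    cluster expression (Fisher exact, Wilcoxon rank-sum), splicing and
    intron-retention diagnostics, and genetic-versus-expression distance
    tree comparison. A synthetic-data generator emulates the statistical
    structure of the study design so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    ape,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    phangorn
Config/testthat/edition: 3
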