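Package: darcall
Title: DNase I Hypersensitivity Enrichment of Transposable-Element Subfamilies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies transposable-element (repeat) subfamilies whose genomic
    instances contribute significantly more open chromatin than expected by
    chance, by comparing their overlap with DNase I hypersensitive sites (DHS)
    against annotation-matched random backgrounds using one-sided binomial
    tests (DHS-associated repeats, "DARs"). Downstream characterisations cover
    repeat age from divergence (Jukes-Cantor), short-read mappability
    simulation, cell-type specificity scores, transcription-factor ChIP and
    motif association (PWM scanning with exact p-values, hypergeometric joint
    tests, a five-feature motif-repeat classifier), permutation Z-scores for
    cis expression, chromatin-state assignment, and conservation and dsQTL
    enrichments. Ships a seeded synthetic-study generator with planted signal
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
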