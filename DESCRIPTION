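Package: teecology
Title: Genomic Ecology of Transposable Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the genomic ecology of transposable elements
    (TEs): base-pair-exact resolution of nested TE annotations, insertion-age
    estimation from LTR-LTR divergence (Kimura two-parameter) and from
    terminal branch lengths of copy phylogenies, assembly of per-copy genomic
    environment features (base composition, methylation profiles, chromatin
    accessibility, recombination rate, expression and tissue specificity),
    and a random-forest model of TE age interpreted through permutation
    importance, per-family correlations and individual conditional
    expectation curves. Includes a synthetic-genome simulator with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    ape,
    randomForest,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
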