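Package: tfbsgrammar
Title: TFBS Orientation and Order Grammar Analysis for MPRA Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying cis-regulatory grammar with massively
    parallel reporter assays (MPRA). Designs combinatorial transcription
    factor binding site (TFBS) tile libraries (homotypic copy-number sweeps,
    heterotypic pair and triplet permutations, all strand-orientation
    vectors, position sweeps and spacing rules), simulates barcode-level
    DNA/RNA counts with planted orientation, order, copy-number and position
    effects, quantifies tile activity as normalized log2 RNA/DNA ratios, and
    runs the grammar statistics battery: orientation strand-asymmetry
    t-tests, copy-number and position Spearman trends, Levene variance
    tests, order effects, one-way ANOVA over orientation configurations, a
    Monte-Carlo orientation-gain test, and GC-skew association. Genomic
    corroboration utilities scan sequences with JASPAR-style PWMs under an
    exact p-value threshold, extract promoters, test consecutive homotypic
    TFBS strand asymmetries and pair order preferences with binomial tests,
    and shuffle sequences preserving dinucleotide content. Strand-aware and
    strand-agnostic lasso models of activity from motif counts are compared
    by cross-validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    car,
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
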