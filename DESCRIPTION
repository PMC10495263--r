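Package: macroloop
Title: Integrative Analysis of MacroH2A Chromatin Domains, Differential
    Enhancers and Promoter-Anchored Chromatin Loops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links broad histone-variant (macroH2A) chromatin domains,
    differential H3K27ac enhancer activity and promoter-capture chromatin
    loops to changes in gene expression. Provides ROSE-style ranked-curve
    classification of chromatin domains and enhancers, cross-sample signal
    normalization and differential enhancer calls, CHiCAGO-score filtered
    loop comparison between conditions (shared/unique loops, adjacent-bin
    shifts, per-gene loop counts), stratified chi-square association tests
    with Pearson residuals, expression-matched control gene sampling,
    metagene and point-centered signal profiles with bootstrap confidence
    intervals, a target-gene intersection, and a seeded synthetic-data
    generator that plants the couplings the analysis is designed to detect.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    methods,
    rtracklayer,
    data.table,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
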