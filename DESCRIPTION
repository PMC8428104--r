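Package: heterosiskit
Title: Heterosis Analysis of Hybrid Thermal Tolerance and Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for mid-parent heterosis in hybrid-parent
    trios under thermal stress. Estimates Arrhenius break temperatures
    from cardiac performance traces by two-segment least-squares
    regression, classifies hybrid gene-expression modes from the d/|a|
    dominance ratio (additive, partial dominance, dominance, over- and
    under-dominance), normalizes RNA-seq counts by trimmed mean of
    M-values, calls control-versus-heat differential expression with a
    documented Welch stand-in test, filters percent-spliced-in (psi)
    divergence of alternative-splicing events, and integrates the
    resulting gene sets with Venn partitions and hypergeometric
    over-representation tests. Includes synthetic-data generators with
    known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
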