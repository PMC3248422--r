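Package: cciRank
Title: Metabolic Pathway Class Ranking from Chemical-Chemical Interaction
    Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Guilt-by-association prediction of the eleven top-level KEGG
    metabolic pathway classes for small molecules.  For a query compound the
    confidence scores of its chemical-chemical interactions (STITCH-style
    weights) with annotated neighbours are summed per pathway class, and the
    eleven classes are returned ranked by descending score.  Includes readers
    for interaction and annotation tables, a stratified 5-fold
    cross-validation harness with per-order accuracy, average label count and
    top-k coverage metrics, a planted-assortativity synthetic benchmark
    generator, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
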