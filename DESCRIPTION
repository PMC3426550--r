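Package: sgaepsilon
Title: Quantitative Genetic-Interaction Scoring for Colony-Array (SGA) Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for quantitative synthetic
    genetic array (SGA) colony-size screens: plate-level normalization from
    inner-perimeter border-control colonies, replicate aggregation with
    outlier rejection, Welch tests of control-versus-query colony sizes,
    fitness estimation relative to the border-control median, digenic and
    trigenic genetic-interaction (epsilon) scoring under a multiplicative
    model, stringent hit classification, distributional and reproducibility
    quality control (Gaussian fit of the epsilon distribution, multi-query
    overlap, dubious-ORF neighbor correlation, external-list overlap), and
    hypergeometric functional enrichment.  Includes a synthetic screen
    generator that emulates the 1536-colony plate design with a two-colony
    border-control perimeter, so the whole pipeline is testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    minpack.lm,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
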