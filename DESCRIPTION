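Package: crisprfate
Title: Analysis of Pooled In Vivo CRISPR Screens with Guide Capture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing pooled CRISPR/Cas9 perturbation screens read
    out by single-cell RNA sequencing with guide capture, as used for in vivo
    fate screens in embryonic tissue. Covers ambient-filtering of guide
    capture UMIs by the per-guide log10 mean minus 2 SD rule, knockdown
    quality control of guides against scramble controls, cross-validated
    guide-by-cluster enrichment and depletion statistics (chi-square adjusted
    residual z-scores and Kullback-Leibler divergence permutation tests),
    regularized-regression perturbation expression signatures with
    permutation p-values, Jaccard comparison of misregulated gene sets with
    local Fisher over-representation analysis, screen design power and guide
    capacity calculations, and per-cell quantification of multiplexed in situ
    (HCR) measurements. Includes a seeded synthetic screen generator with
    planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    fgsea,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
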