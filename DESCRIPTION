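Package: obsmets
Title: Oxidative Balance Scores and Gene-Environment Interaction Analysis
    for Metabolic Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs oxidative balance scores (OBS) from pro- and
    antioxidant exposures under equal, regression-coefficient, and
    principal-component weighting; classifies metabolic syndrome and its
    five components under NCEP-ATP III criteria with Korean waist cut-offs;
    fits quartile logistic association, trend, ROC/AUC, and inflammation
    marker models; runs a genome-wide SNP-by-OBS interaction scan with
    Benjamini-Hochberg q-values; and performs significance-proportion
    corrected gene-set enrichment (i-GSEA style) of interaction p-values
    with SNP-label permutation FDR. Ships a synthetic cohort and genotype
    generator with planted interaction effects so the whole chain is
    testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
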