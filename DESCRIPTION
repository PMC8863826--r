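Package: fractionvaf
Title: Tumor-Cell Enrichment Analysis and VAF-Ratio Germline
    Classification for FFPE Panel Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of targeted-panel variant calls from
    formalin-fixed paraffin-embedded (FFPE) tumor sections that have been
    separated into tumor-enriched and tumor-depleted (residual) cell
    fractions.  Implements a variant filter cascade for low tumor-content
    specimens, cross-fraction matching with Venn-group assignment,
    quantification of the enrichment effect on variant allele frequency
    (VAF), classification of germline versus somatic origin from the
    tumor/residual VAF ratio via ROC thresholding without a matched blood
    sample, and a simplified grid-likelihood tumor-purity estimator.  A
    synthetic two-fraction cohort simulator with full ground truth makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
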