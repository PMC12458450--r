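Package: bishot
Title: Bayesian Informative Shrinkage Hypothesis Testing for Differential
    Omics Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential analysis of gene expression (bulk and single-cell
    RNA-seq) that incorporates per-gene prior effect estimates from another
    platform or species through a heteroscedastic global-local shrinkage
    prior. Composite null hypotheses are tested with the Bayesian Credible
    Ratio computed from posterior draws of a blocked Gibbs sampler with
    slice-sampled shrinkage scales, and multiplicity is controlled through
    a sign-adjusted false discovery rate with a data-driven rejection
    threshold. Includes a two-component (dropout plus continuous) model for
    single-cell data, a simulation harness, and file-based input/output for
    count matrices and prior tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
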