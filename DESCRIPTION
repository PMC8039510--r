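Package: mmpop
Title: Hierarchical Minimal-Model Analysis of Glucose Effectiveness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of the Bergman glucose minimal model under
    measured-insulin forcing, maximum-likelihood population (nonlinear
    mixed-effects) estimation via a Monte-Carlo EM algorithm with an
    importance-sampling E-step, forward covariate-model selection gated by
    likelihood-ratio tests, and partitioning of net glucose disposal into
    non-insulin-dependent and insulin-dependent components. Includes a
    synthetic IVGTT / insulin-modified-IVGTT cohort generator for method
    validation and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
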