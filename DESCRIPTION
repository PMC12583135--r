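Package: pedherit
Title: Variance-Components Heritability from Extended Family Histories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates additive genetic (h2), shared household (c2) and
    unique environment (e2) variance proportions for binary brain-disease
    phenotypes observed in large collections of extended pedigrees, as
    reported through family-history registries.  Provides recursive kinship
    matrices and household matrices per family, Gaussian variance-components
    maximum likelihood with boundary-corrected likelihood-ratio tests,
    family-level bootstrap confidence intervals with distribution-shape
    diagnostics (normality and bimodality of the bootstrap estimates),
    Benjamini-Hochberg correction across diseases, and a liability-threshold
    family-history simulator with gene dropping for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
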