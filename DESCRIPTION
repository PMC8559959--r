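Package: flexcfdr
Title: Conditional False Discovery Rates with Arbitrary Continuous Covariates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Covariate-informed multiple testing for GWAS summary statistics
    via the conditional false discovery rate (cFDR). P-values for a principal
    trait are combined with a continuous auxiliary covariate (for example
    functional genomic scores or p-values from a related trait) through a
    boundary-reflected bivariate kernel density estimate and an Efron-style
    local false discovery rate, and each p-value--covariate pair is mapped to
    a "v-value": the probability, under the null, that a fresh pair falls in
    the rejection (L-) region of the observed pair. The v-values behave like
    p-values and can be passed to any standard error-rate controlling
    procedure such as Benjamini-Hochberg. The package can be applied
    iteratively to leverage multi-dimensional covariates, and includes a
    simulation harness that emulates block-correlated GWAS Z-scores with
    configurable auxiliary-covariate scenarios for assessing sensitivity,
    specificity and FDR control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
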