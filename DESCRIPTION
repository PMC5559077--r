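Package: herra
Title: Heritability Estimation Using Regularized Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates narrow-sense SNP heritability from GWAS-scale genotype
    data using a regularized-regression approach (HERRA). SNPs are first
    screened with marginal (sure independence screening) or joint (iteratively
    thresholded ridge regression) screeners, the environmental variance is
    estimated by a refitted cross-validation scheme (lasso selection on one
    half-sample, ordinary least-squares refit on the other, roles switched and
    averaged), and heritability is formed as one minus the ratio of the
    environmental to the total outcome variance. Supports continuous,
    dichotomous (with liability-scale conversion and case-control
    ascertainment correction) and right-censored age-at-onset outcomes (via
    inverse-probability-of-censoring weighting), weighted-bootstrap standard
    errors, PLINK bed/bim/fam input, and a synthetic-data generator for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    survival,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
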