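Package: dimorphr
Title: Quantitative Genetics of Sexual Dimorphism in Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how sexual dimorphism in gene expression
    evolves under sexually antagonistic and concordant selection. Implements
    the two-sex multivariate breeder's equation on sex-specific genetic
    covariance (G) matrices with a cross-sex B block, closed-form one- and
    two-trait predictions of dimorphism change, evolvability, respondability
    and conditional responses, and matrix-symmetrization experiments.
    Provides a gene-wise pipeline for inbred-line expression panels
    (mixed-model screening for genetic variance, least-squares line means,
    dimorphism and bias classification, per-gene genetic parameters,
    aggregate cross-gene correlation statistics, tissue specificity),
    line-level bootstrapped multiple regression of dimorphism on G-derived
    predictors, principal-component trait construction within bias classes,
    moment-based estimation of the trait-level G matrix with AICc rank
    selection and Wishart uncertainty resampling, and a synthetic
    inbred-line panel generator with known genetic architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
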