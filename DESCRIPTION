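Package: bacinb
Title: Before-After-Control-Impact Analysis of Multivariate Count Data with
    Negative Binomial Models and Bootstrap Power
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing Before-After-Control-Impact (BACI) field
    experiments on multivariate taxon-count data, as used to assess non-target
    effects of biopesticide applications on ground-dwelling arthropod
    communities. Provides pooling and subsample extrapolation of raw count
    tables, per-taxon negative binomial generalized linear models combined
    into a multivariate fit, AIC comparison of nested models, analysis of
    deviance with row-resampling p-values, BACI effect estimates with
    replicate-based standard errors, bootstrap retrospective and prospective
    power analyses built on the AIC decision rule, and a synthetic-data
    generator that emulates the paired-plot, two-habitat, multi-occasion
    sampling design so every stage runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    ggplot2,
    withr
Config/testthat/edition: 3
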