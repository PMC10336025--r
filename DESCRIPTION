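Package: zibcopula
Title: Copula Models with Zero-Inflated Beta Margins for Microbial
    Covariation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation and testing of pairwise dependence between
    microbial taxa from relative-abundance data using a Frank copula
    with zero-inflated beta mixture margins. Marginal models allow
    covariate adjustment of the zero-inflation probability, beta mean
    and dispersion through configurable link functions. Dependence is
    estimated by a two-stage (inference-for-margins) maximum-likelihood
    procedure with jackknife variance estimation, and tested with a
    rescaled likelihood-ratio statistic that is asymptotically
    chi-squared with one degree of freedom. All-pairs analyses are
    corrected by the Benjamini-Yekutieli procedure and assembled into
    theta-weighted covariation networks with hierarchical clustering,
    graph summaries, Erdos-Renyi null comparison and bootstrap
    consistency assessment. A Rosenblatt-transform simulator generates
    zero-beta mixture data under Frank or Gaussian copula dependence,
    including unit-sum multivariate abundance tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'fit-margin.R'
    'frank-copula.R'
    'io.R'
    'joint-density.R'
    'links.R'
    'lrt.R'
    'network.R'
    'simulate.R'
    'two-stage.R'
    'zib-distribution.R'
    'zibcopula-package.R'
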