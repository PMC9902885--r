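Package: gencorrnet
Title: Genetic Correlation Networks from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates SNP heritability and pairwise genetic correlations
    from GWAS summary statistics by LD-score regression with block-jackknife
    standard errors and a cross-pair sampling covariance; assembles the
    trait-by-trait genetic correlation matrix; aligns reverse-coded traits by
    the loadings of the first principal component; controls the false
    discovery rate across all trait pairs; clusters traits with the Louvain
    method on absolute genetic correlations; quantifies cluster stability by
    multivariate-normal resampling of the correlation matrix; and derives the
    effective number of independent tests from the spectral decomposition of
    a (possibly pairwise-complete) correlation matrix. A multi-trait
    summary-statistic simulator with known heritabilities, genetic
    correlations, and confounding intercepts makes the whole chain testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'accessors.R'
    'synth.R'
    'sumstats.R'
    'ldsc.R'
    'corrmatrix.R'
    'cluster.R'
    'stability.R'
    'effdf.R'
    'pipeline.R'
    'gencorrnet-package.R'
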