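Package: seqlmm
Title: Linear Mixed Models for RNA-Seq Studies with Correlated Observations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential expression analysis for RNA-Seq designs that induce
    correlation between observations (longitudinal sampling, paired designs,
    repeated measures). Counts are normalized with median-of-ratios size
    factors and a closed-form variance-stabilizing transformation driven by a
    parametric mean-dispersion trend; each gene is then analyzed with a linear
    mixed model fit by restricted maximum likelihood, using either random
    effects or a compound-symmetric/unstructured marginal residual covariance.
    Contrasts are tested with Satterthwaite-degree-of-freedom t- and F-tests
    and Benjamini-Hochberg adjustment, with singular-fit reporting and
    exclusion. The package also ships the negative-binomial GLMM simulator and
    the permutation-spike benchmark used to assess type-I error, false
    discovery rate, and power, plus residual diagnostics and a CPM filter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    parallel,
    Matrix,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    lmerTest,
    nlme,
    car,
    DESeq2,
    SummarizedExperiment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
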