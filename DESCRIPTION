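Package: deazoib
Title: Two-Stage Hospital Efficiency Analysis with DEA and Multilevel
    Zero-One Inflated Beta Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two-stage analysis of the technical efficiency of
    decision-making units such as hospitals. Stage one scores each unit
    with an output-oriented, variable-returns-to-scale (BCC) data
    envelopment analysis, yielding pure technical efficiency (PTE) in
    (0, 1] and frontier membership. Stage two relates PTE to unit- and
    group-level covariates through a Bayesian multilevel zero-one
    inflated beta regression fitted by adaptive Metropolis-within-Gibbs
    MCMC, with rank-normalized split R-hat and bulk/tail effective
    sample size diagnostics, posterior credible intervals, positive and
    negative coefficient probabilities, and effect measures on the ratio
    scale (ratio of mean efficiency indices; odds ratio of frontier
    membership). Includes synthetic-data generators with known
    parameters for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rjags,
    yaml
Config/testthat/edition: 3
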