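Package: phylopipe
Title: Multi-Gene Supermatrix Phylogenomics with Parsimony, Likelihood
    and Bayesian Support Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multi-locus nuclear phylogenomics of shallow
    radiations: mining single-copy markers from a proteome by all-vs-all
    self-comparison with similarity/coverage filters, building partitioned
    supermatrices with descriptive statistics (variable and
    parsimony-informative sites, base-composition homogeneity, Kimura
    two-parameter distances, Ti/Tv), maximum-parsimony inference with
    nonparametric and variable-length bootstrap and Bremer / partitioned
    Bremer support, maximum-likelihood inference under JC/K80/HKY/GTR
    with invariant sites and discrete-gamma rates (AIC model selection,
    clock likelihood-ratio test, RELL-based KH/SH/WSH topology tests,
    strict-clock fossil scaling), partitioned Bayesian MCMC with
    harmonic-mean marginal likelihoods and Bayes-factor comparison of
    partitioning strategies, and Mk-model ancestral-state reconstruction
    for discrete traits. Includes simulators for sequence, proteome and
    trait data with machine-readable truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
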