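Package: parallevol
Title: Detecting Parallel Molecular Evolution on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting parallel and convergent amino-acid evolution
    on fixed phylogenies, built around a Felsenstein pruning likelihood engine
    for empirical amino-acid models with invariant-sites and discrete-gamma
    rate heterogeneity and for Goldman-Yang codon models with per-branch dN/dS.
    Implements per-site log-likelihood comparison of competing topologies
    (d values) with greedy minimal-site-removal, marginal empirical-Bayes and
    Fitch parsimony ancestral reconstruction, Zhang-Kumar expected counts and
    Poisson tests for parallel and convergent substitutions between branch
    pairs, codon branch-model likelihood-ratio tests with Bonferroni
    correction, and phylogenetically independent contrasts for correlating
    substitution counts with continuous traits. Includes simulators for
    alignments, codon alignments, and Brownian traits so every stage can be
    exercised on synthetic data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    phangorn,
    Biostrings,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
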