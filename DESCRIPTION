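Package: mscflow
Title: Simulation and Inference of Cross-Species Gene Flow Under the
    Multispecies Coalescent
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking detection and estimation of cross-species
    gene flow from multilocus sequence data. Provides a structured-coalescent
    simulator for species networks with a pulse introgression event (MSC-I) or
    continuous migration bands (MSC-M) and Jukes-Cantor sequence evolution;
    exhaustive maximum-likelihood gene-tree estimation for quartets; the
    summary tests used in comparative studies of gene flow (discordant-count
    test, branch-length test, a shifted-exponential mixture test on internal
    branch lengths, and the ABBA-BABA D-statistic with block jackknife); a
    full-likelihood Bayesian MCMC engine for quartet introgression models with
    highest-posterior-density summaries and Savage-Dickey Bayes-factor tests
    of gene flow; and a benchmark harness computing power, bias, credible
    interval width and coverage over simulation grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    stats,
    tibble,
    dplyr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
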