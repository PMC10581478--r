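Package: edrhythms
Title: Circadian Rhythms of Epileptiform Discharges: Phenotyping and
    Stochastic Brain-Network Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing and modelling the 24-hour distribution of
    epileptiform discharges (EDs) in generalized epilepsy. The package
    clusters subjects into circadian ED phenotypes from hourly rate
    profiles (k-means on pairwise correlations with Calinski-Harabasz
    model selection), simulates a stochastic bistable brain network built
    on the subcritical Hopf normal form whose node excitability is forced
    by sleep-stage and cortisol signals, expands small healthy-control
    input sets into virtual cohorts (SMOTE augmentation of cortisol
    profiles, hypnogram resampling), and fits the relative contribution of
    the sleep and cortisol drivers to observed hourly ED histograms by
    residual-sum-of-squares grid search and Metropolis-Hastings sampling.
    Synthetic generators for hypnograms, cortisol profiles and
    two-phenotype ED cohorts make the full pipeline runnable without
    clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    lme4
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
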