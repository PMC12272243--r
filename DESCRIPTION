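Package: burstnet
Title: Dynamic Oscillatory Network Analysis of Electrophysiological Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying and characterising transient oscillatory
    networks in source-space electrophysiological (M/EEG) parcel time series.
    Simulates bursting oscillatory networks with Markov-chain burst dynamics,
    prepares data by time-delay embedding and PCA, and fits two dynamic
    network models: a time-delay-embedded hidden Markov model with mutually
    exclusive states and a dynamic mixture of mode covariances with
    simplex-constrained mixing coefficients that allows temporally
    overlapping networks. Post-hoc tools derive frequency-resolved network
    descriptions (multitaper state spectra, GLM mode spectra, power maps,
    coherence networks, non-negative matrix factorisation band selection),
    compute task-evoked network responses and conventional Morlet
    time-frequency responses, and assess group-level significance with
    max-statistic permutation GLM tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
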