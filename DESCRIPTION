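Package: numit
Title: Null-Model Normalisation of Partial Information Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compute and compare Partial Information Decomposition
    (PID) atoms across systems with different total mutual information.
    Implements the minimal-mutual-information (MMI) decomposition for
    linear-Gaussian source-target systems and stationary vector
    autoregressions (VAR), the naive normalisation by total mutual
    information (NMI), and NuMIT: a null-model normalisation that scores
    each atom as its quantile within an ensemble of random systems
    constrained to the same total mutual information. Includes null-ensemble
    construction for both Gaussian and VAR models (random and data-driven
    variants), VAR fitting from epoched multivariate time series,
    autocovariance computation via the discrete Lyapunov equation, seeded
    synthetic experiments, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
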