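Package: lfpstates
Title: Transient Spectral States in Subthalamic Local Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transient spectral states in deep-brain local field
    potential (LFP) recordings with a time-delay embedded hidden Markov model
    (TDE-HMM), assigns states to canonical frequency bands (theta, alpha, low
    beta, high beta) by correlation with band-limited Hilbert envelopes, and
    summarises state dynamics (fractional occupancy, life time, interval time,
    occurrence rate, transition probabilities). Includes the standard
    percentile-thresholding burst detector as a comparator, ridge regression
    with leave-one-out cross-validation linking state features to hemibody
    motor scores, sign-flip permutation tests with false-discovery-rate
    correction, and a synthetic cohort generator that plants bursty band-limited
    oscillations over 1/f background with clinical scores coupled to the true
    burst statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
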