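Package: erkchannel
Title: Information Transmission Through Pulse-Interval Codes in the MAPK/ERK Pathway
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how much information sequences of short EGF
    pulses can push through the MAPK/ERK signalling pathway. Provides the exact
    combinatorial theory of refractory pulse-interval transcoding (grouping of
    input sequences, Fibonacci-type counts of accurately transmitted sequences,
    asymptotic channel capacity), a calibrated ODE model of the pathway driven
    by binary EGF pulse trains with extrinsic lognormal noise, a fast surrogate
    stochastic channel for estimator validation, a weighted k-nearest-neighbour
    (Kraskov-type) mutual-information estimator for discrete inputs and
    continuous multi-dimensional responses, channel-capacity maximization over
    input distributions by adaptive stochastic gradient ascent, and experiment
    drivers that tabulate bitrates across pulse frequencies and noise levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
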