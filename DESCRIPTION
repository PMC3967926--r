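Package: wtahmm
Title: Stochastic Winner-Take-All Spiking Networks as Online Hidden Markov
    Model Learners
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Event-driven simulation of stochastic winner-take-all (WTA)
    spiking circuits whose dynamics realize forward sampling in a hidden
    Markov model (HMM), together with the spike-timing-dependent plasticity
    (STDP) rule that implements the stochastic M-step of online
    expectation-maximization, and its refinement by rejection and importance
    sampling with synaptic eligibility traces.  Includes exact discrete-HMM
    reference machinery (teacher sampling, scaled forward algorithm,
    Baum-Welch), the bidirectional mapping between the discrete-time network
    and a standard HMM, finite-state-grammar stimulus generators with Poisson
    rate-pattern encodings, and analysis readouts: peri-event time
    histograms, peak-time sorting, rank-order replay correlation,
    selectivity profiling, jPCA rotational-plane projection, linear readout,
    and likelihood-threshold sequence classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    e1071,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
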