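Package: spikemix
Title: Spike-Triggered Mixture Models for Single-Neuron System Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Probabilistic encoding models for binned single-neuron spike
    trains: linear-nonlinear-Bernoulli generalized linear models, quadratic
    models, the spike-triggered mixture model (STM) whose log-odds is a soft
    maximum over per-component quadratic stimulus responses, and its factored
    low-rank variant. Models are initialized generatively (Gaussian-mixture
    class conditionals fitted by expectation maximization, interspike-interval
    histograms converted to a spike-history filter through Bayes' rule) and
    fine-tuned discriminatively by quasi-Newton maximization of the Bernoulli
    conditional likelihood with optional early stopping. Includes an
    evaluation suite (held-out cross-entropy in bits per bin and bits per
    second, mutual-information lower bounds with spike-history decomposition,
    a leave-one-trial-out PSTH oracle, explained variance) and a simulator
    emulating low-pass-filtered Gaussian noise stimulation experiments with
    frozen and unfrozen trials.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
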