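Package: metaspike
Title: Meta-Learning of Neuromodulated Synaptic Plasticity in Spiking
    Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training spiking neural networks whose synapses learn
    online through neuroscience-derived plasticity rules.  Provides discrete-time
    current-based leaky integrate-and-fire (CUBA) neuron layers with surrogate
    spike gradients, pair- and triplet-based spike-timing-dependent plasticity
    with additive, multiplicative and power-law weight dependence, eligibility
    traces, and three-factor neuromodulated weight updates.  A bilevel training
    loop optimises the plasticity and neuromodulation parameters by
    backpropagation through time across whole episodes, so that within-episode
    learning is carried entirely by the plastic synapses.  Includes episode
    generators for a permuted one-shot cue-association task and a sequential
    one-shot character-recognition task on a synthetic glyph corpus, evaluation
    harnesses with exact binomial intervals, and plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    generics,
    ggplot2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse,
    png
Config/testthat/edition: 3
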