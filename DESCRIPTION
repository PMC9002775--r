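Package: eegrnn
Title: Random Neural Network Classification of Epileptic EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end epileptic seizure classification from multichannel
    EEG using the Gelenbe random neural network, a queueing-theoretic spiking
    model whose steady-state neuron activations admit a closed product form.
    Provides windowed segmentation of EEG recordings, per-channel statistical
    feature extraction (standard deviation, kurtosis, skewness, mean) with
    min-max normalization, an exact feedforward steady-state solver with a
    discrete-event spiking simulator as an independent oracle, projected
    gradient-descent training, comparison baselines (extremely randomized
    trees, a convolutional-network shape and parameter calculator, channel
    attention and cosine-transform operators), cross-validated evaluation
    with one-vs-rest multiclass metrics, a seeded synthetic EEG generator,
    and a European Data Format (EDF) reader and writer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    ranger,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
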