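Package: sincvoice
Title: Learnable Sinc Filterbank Networks for Pathological Voice Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Interpretable classification of voice disorders from raw
    sustained-vowel waveforms. Implements a learnable sinc band-pass
    filterbank front end whose only parameters are per-channel low and high
    cutoff frequencies, the convolutional/fully-connected network stacks it
    feeds, one- and two-dimensional convolutional baselines, a source-filter
    synthesizer of pathological /a/ vowels (jitter, shimmer, high-frequency
    noise, amplitude modulation), cross-validated training with utterance
    level aggregation, confusion-matrix metrics including unweighted average
    recall, and filter interpretability analyses based on averaged Welch
    power spectral densities of filterbank outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Rtsne,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
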