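Package: laseg
Title: Learning-Automaton Configuration Search for Dense Encoder-Decoder
    Segmentation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic configuration of an encoder-decoder dense
    convolutional network for neonatal brain tissue segmentation using a
    team of variable-structure learning automata.  A learning automaton is
    attached to every configurable layer (19 convolutions, 2 encoder
    pooling stages); each automaton holds a probability vector over its
    discrete hyperparameter actions and is updated with linear
    reward-penalty operators driven by the Dice quality of candidate
    networks.  Includes the configurable CNN itself (dense blocks of
    convolution, batch normalisation and ReLU with a CPU training engine),
    Dice and average-surface-distance segmentation metrics, a multimodal
    tissue-phantom generator for desk-scale experiments, deterministic
    oracle environments for testing the search loop, NIfTI volume I/O and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
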