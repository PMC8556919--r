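Package: specsimnet
Title: Siamese Neural Network Prediction of Structural Similarity from
    Tandem Mass Spectra
Version: 0.1.0
Authors@R:
    person("specsimnet", "developers", email = "specsimnet@example.org",
           role = c("aut", "cre"))
Description: Predicts fingerprint-based structural similarity (Tanimoto or
    Dice) between pairs of tandem mass (MS/MS) spectra directly from binned
    peak vectors using a Siamese dense neural network with a cosine head.
    Includes MGF/MSP/JSON spectrum readers, peak filtering and fixed-grid
    binning, compound-level similarity label matrices from molecular
    fingerprints, balanced pair sampling across similarity-score bins with
    on-the-fly spectrum augmentation, a hand-implemented trainable dense
    network (Adam, batch normalization, dropout, early stopping),
    Monte-Carlo-dropout uncertainty estimation (median and interquartile
    range of score ensembles), evaluation procedures (per-similarity-bin
    RMSE, precision/recall for high-similarity retrieval, same-compound
    aggregation), a synthetic spectral-library generator with a planted
    spectrum-fingerprint correlation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
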