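Package: prespeech
Title: Time-Resolved Semantic-Category Decoding of Prespeech High-Gamma
    Intracranial Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for decoding semantic category (body versus
    nonbody words) from trial-structured intracranial recordings during the
    prespeech interval. Provides a synthetic event-related signal generator
    with known planted effects, preprocessing (common average reference,
    notch filtering, impedance-based channel exclusion, interictal-discharge
    trial rejection, 70-170 Hz envelope extraction, prestimulus baseline
    normalization), sliding-window feature extraction with leakage-controlled
    channel selection, group-level time-resolved classification per cortical
    region, dual permutation validation (label-shuffle and time-shuffle) with
    Benjamini-Hochberg false discovery rate control, and cross-temporal
    regression coupling maps with seed-and-grow cluster significance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    e1071,
    MASS,
    randomForest,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
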