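Package: chirsep
Title: Physics-Based Prediction of Diastereomeric Salt Resolutions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the success of chiral resolutions by diastereomeric
    salt crystallisation. Builds weighted atom-density representations of
    enantiomer-resolving-agent complexes from conformer ensembles, compresses
    them, forms mean and absolute-difference streams over the two
    diastereomeric salts, and scores experiments with a dual-stream attention
    network trained in two stages (regression pre-training, classification
    fine-tuning on a low-noise subset). Includes racemate-grouped
    cross-validation, enrichment-factor and average-precision evaluation,
    attention versus crystal-contact analysis, and a synthetic fixture
    generator with a planted, recoverable signal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ChemmineR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
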