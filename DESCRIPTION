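Package: chezodr
Title: Continuous Protein Disorder Prediction from Sequence Using CheZOD Z-Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based prediction of continuous-valued protein disorder
    expressed as NMR chemical-shift-derived CheZOD Z-scores. Provides readers
    and writers for FASTA and CheZOD-style per-residue Z-score files, the
    staged database-balancing filters and sequence-identity stripping used to
    assemble balanced order/disorder training sets, a per-residue sequence
    feature matrix (amino-acid composition, physico-chemical,
    secondary-structure propensity, pattern, and optional alignment-profile
    features), a small feed-forward neural-network Z-score regressor trained
    as a 10-fold cross-validation ensemble with calibrated prediction
    uncertainty, a two-component skew-normal mixture model of the Z-score
    distribution that converts predicted Z-scores into per-residue disorder
    probabilities, evaluation metrics for continuous and binary disorder
    prediction, permutation feature importance, and a seeded generator of
    synthetic CheZOD-like databases with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
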