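Package: fnacmet
Title: Untargeted Metabolomic Classification of Thyroid FNAC Liquid-Cytology Fluids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for diagnosing thyroid-nodule malignancy from
    untargeted LC-MS metabolomic profiles of fine-needle-aspiration
    liquid-cytology fluids. Starting from per-run peak lists, the package
    aligns features across runs, annotates ions against a compound database
    by monoisotopic mass, applies intensity and blank-ratio quality filters,
    and selects a compact ion signature with a supervised autoencoder using
    a step-by-step top-down elimination. PLS-DA with VIP scores,
    label-permutation significance testing, and SVM/random-forest comparators
    are provided together with a repeated stratified cross-validation
    harness. A synthetic-cohort generator with planted ground truth makes
    every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
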