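Package: voicebdi
Title: Depression Severity Prediction from Voice-Diary Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for predicting continuous
    depression severity (Beck Depression Inventory, BDI) from weekly
    voice-diary transcripts: a synthetic cohort generator emulating the data
    structure of smartphone voice-diary studies (two diagnostic groups,
    right-skewed adherence, autocorrelated within-person severity,
    theme-structured transcripts with role-tagged tokens), participant-grouped
    nested cross-validation of a z-score/PCA/SVR pipeline over multimodal
    feature matrices, stacked late fusion with a ridge meta-learner,
    label-shuffle and sign-flip permutation inference, calibration and
    Bland-Altman agreement analysis, controlled linguistic perturbations of
    transcripts, idiographic change tracking, and an embedding-space topic
    layer with class-based TF-IDF keywords and topic-symptom statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    e1071,
    rlang
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
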