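Package: acamspeech
Title: Severity-Aware Keyword Classification and Aphasia-Specific
    Class Activation Mapping for Disordered Speech
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale toolkit for explainable keyword classification in
    aphasic speech. Provides a seed-reproducible synthetic disordered-speech
    generator with planted, ground-truth-annotated anomalies (pauses, phoneme
    substitutions/deletions/insertions, word-boundary shifts) coupled to a
    continuous severity score; a small spectrogram keyword classifier with
    feature-wise linear modulation (FiLM) severity conditioning and exact
    hand-written gradients; a multimodal aphasia filter built from
    voice-activity pause detection, edit-distance phoneme alignment and
    word-boundary gap analysis; a dual-stream adaptive-perturbation class
    activation mapping (A-CAM) attribution core with dual positive filtering,
    filter gating and overlap-aware segment aggregation; and faithfulness and
    validation metrics (deletion/insertion AUPC, ADCC, IoU/Dice,
    Mann-Whitney U, Cohen's d, Spearman rank correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    signal,
    jsonlite,
    yaml,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
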