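Package: p300tl
Title: Transfer Learning for P300 Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Cross-subject transfer learning for P300 event-related potential
    detection in EEG brain-computer interfaces. Implements a compact
    convolutional network for deep feature extraction with frozen-layer
    fine-tuning, Euclidean-space alignment of feature distributions between
    source and target subjects, Euclidean-distance source sample selection to
    avoid negative transfer, and a discriminative restricted Boltzmann machine
    classifier. Includes stimulus-locked preprocessing (band-pass filtering,
    decimation, epoching), 6x6 matrix-speller character decoding with
    information transfer rate and balanced-accuracy metrics, and a synthetic
    session generator for the row/column speller and rapid serial visual
    presentation paradigms so that the full pipeline can be exercised without
    external recordings.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
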