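Package: timbral
Title: Timbre Descriptors and Emotion-Rating Models for Short Instrument Tones
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Synthesizes short orchestral-register test tones, extracts a
    23-descriptor timbre representation (ERB-rate spectral moments and shape
    statistics, spectral variation, and temporal-envelope attack descriptors),
    prunes collinear descriptors, and models mean emotion ratings (valence,
    tension arousal, energy arousal) with partial least-squares regression and
    a small backpropagation network, including five-fold cross-validation,
    signed connection-weight feature contributions, and model-comparison
    tables. Includes a synthetic stimulus and rating generator for end-to-end
    validation when the original audio and participant data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
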