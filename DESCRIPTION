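Package: finchsong
Title: Detection and Characterisation of Vocal Repertoire Expansion in Zebra Finch Song
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting and characterising the addition of
    novel syllable types to the crystallised song of adult zebra finches.
    Provides a synthetic song generator with ground-truth annotations,
    amplitude-threshold syllable segmentation with a minimum-duration filter,
    per-frame spectral features (pitch, goodness of pitch, Wiener entropy,
    frequency and amplitude modulation, amplitude), percent-similarity scoring
    between syllable renditions with bootstrap ECD confidence bands, a
    1.96-sigma similarity criterion for syllable novelty with an
    embedding/density-clustering cross-check, and syllable-sequence statistics
    (transition matrices, sequence linearity, sequence consistency, and the
    positioning of novel syllables relative to motif ends).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
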