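Package: ffvit
Title: Frequency-Domain Vision Transformer for Endomicroscopy Probe Orientation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Regression of the two-axis tilt of a probe-based confocal laser
    endomicroscopy (pCLE) probe relative to the tissue-surface normal from
    single grayscale frames. Implements a frequency-domain patch-embedding
    vision transformer with diagonally masked, temperature-scaled
    self-attention, a blur-mapping cross-attention module that fuses per-patch
    no-reference blur scores into the token stream, and a pyramid angle
    regressor with deep multi-scale supervision. Includes a synthetic pCLE
    frame generator with tilt-dependent spatially varying blur, a suite of
    no-reference focus metrics with a distortion-rate working-range analysis,
    training via AdamW with an L1 multi-scale objective, evaluation metrics
    (MAE, error spread, rotation-direction accuracy), and the pivot-point
    kinematics that convert a corrective rotation into base translations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    png,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
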