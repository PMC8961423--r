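Package: kymolyze
Title: Single-Molecule Kymograph Analysis of Transcription and Origin Licensing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-molecule TIRF kymographs of
    transcribing RNA polymerase and origin-licensing factors (ORC, OCCM,
    MCM double hexamers) on flow-stretched DNA. Provides trajectory
    extraction from kymograph images (field flattening, subpixel Gaussian
    peak localization with annulus background subtraction, greedy linking,
    drift correction), kinetic change-point segmentation of position and
    intensity traces, burst transcription-rate and pause statistics,
    collision-outcome and terminator-stability classification, MSD-based
    diffusion estimation, photobleaching step counting and copy-number
    estimation, bootstrap errors and kernel density summaries, together
    with a synthetic-data generator with named condition presets and
    per-molecule ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
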