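Package: ehtkit
Title: Analysis Toolkit for Stretch-Conditioned Engineered Heart Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and morphometry for engineered heart tissue
    (EHT) experiments under progressive stretch conditioning. Converts
    continuous force recordings into per-beat contractile features and
    protocol-level summaries (conditioning time courses, stretch-step
    responses, hypoxia residual force, stimulation threshold), computes
    isometric biomechanics (Frank-Starling curves, passive elastic modulus,
    specific force, force-frequency relationship, drug responses), extracts
    calcium-transient and action-potential morphometrics, and runs a
    confocal-image pipeline (nucleus segmentation, membrane-seeded watershed,
    sarcomeric alpha-actinin thresholding, myocyte filtering, principal-axis
    cell geometry, neighbor-based orientation dispersion, sarcomere-length
    periodicity). Seeded synthetic-data generators with exact ground truth
    emulate every supported modality for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    signal,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
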