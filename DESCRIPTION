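Package: locspeed
Title: Acquisition-Speed Planning and Fit-Quality Classification for
    Localization Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for planning single-molecule localization microscopy
    (PALM/STORM) experiments and for auditing the resulting localization
    tables. Implements a closed-form model of how the local dimensionality
    of a labelled structure (point, strand or extended patch) sets the
    minimum number of camera frames needed to reach a target localization
    density, together with the optimal per-frame activation density. Ships
    a fluorophore photoswitching and EMCCD camera simulator, a reference
    single-emitter Gaussian localizer with a two-emitter separation sweep
    for estimating the exclusion radius, per-localization patch features
    with PCA compression, a user-trainable random-forest classifier that
    flags overlap artefacts (good / background / too dense), and Fourier
    ring correlation resolution estimation over random half-splits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    minpack.lm,
    randomForest,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
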