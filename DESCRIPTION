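Package: opponentprf
Title: Opponent Visuospatial Coding Analysis with Signed-Amplitude pRF Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying opponent visuospatial coding in fMRI data.
    Simulates bar-sweep retinotopic mapping stimuli and event-related task
    designs, fits signed-amplitude two-dimensional Gaussian population
    receptive field (pRF) models to voxel timeseries by exhaustive grid
    search, and classifies voxels as positive (activated) or negative
    (deactivated) by the sign of the fitted amplitude. Builds rectangular
    positive-by-negative representational dissimilarity matrices (1 - Pearson
    r) from mapping and task timeseries, correlates them, and tests the
    association with a visuospatial matching analysis and a label-shuffle
    bootstrap null. Includes a synthetic-data generator with known ground
    truth and tunable opponency strength, group-level inference helpers, and
    an end-to-end seeded pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    RNifti,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
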