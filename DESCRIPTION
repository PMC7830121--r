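Package: msldp
Title: MS-Lesion Pattern Discrimination Plots from Directional Variograms
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the three-dimensional spatial structure of binary
    white-matter lesion masks (multiple sclerosis lesion masks in Montreal
    Normal Brain geometry) with two-point geostatistics. Computes directional
    empirical variograms along the three grid axes, fits an exponential
    variogram model per direction by nonlinear least squares, and summarizes
    each lesion pattern by the natural logarithms of the mean model range
    (spatial continuity) and mean sill (lesion-load proxy). Provides a batch
    pipeline over NIfTI-1 and Analyze-7.5 volumes producing an ASCII
    parameter table (.var), per-volume variogram plots, and the Lesion
    Pattern Discrimination Plot and its per-direction component plot as PNG
    graphics, together with synthetic lesion-scene generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    RNifti,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    png,
    oro.nifti,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'fixtures.R'
    'image_io.R'
    'ldp_output.R'
    'msldp-package.R'
    'pipeline.R'
    'variography.R'
    'variomodel.R'
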