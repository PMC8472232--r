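Package: beadband
Title: Multiplexed Bead Immunoassay Quantification in Variable-Height Microfluidic Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for bead-based fluorescence immunoassays run in
    variable-height microfluidic channels, where antibody-coated beads of
    different diameters trap at the channel position whose ceiling height
    matches their diameter and form analyte-specific detection bands.
    Provides a channel design and lubrication-flow model (trap positions,
    multiplexing capacity, hydraulic resistance, design-rule checks), a
    synthetic micrograph generator with known ground truth (bead
    populations, saturable binding response, spectral crossover, bead
    carryover, illumination gradients, debris, and camera noise), the
    masked RFU per bead-area quantification statistic with
    pseudo-flat-field and background correction, bead sizing from
    maximum-intensity projections, assay statistics (four-parameter
    logistic standard curves, limits of detection, intra- and inter-assay
    coefficients of variation, crossover false-positive testing, method
    comparison), a reagent stoichiometry calculator, and an end-to-end
    simulation workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
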