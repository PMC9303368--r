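Package: mcpalm
Title: Motion-Corrected PALM Analysis of Correlative Single-Molecule and
    Locus Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for correlative conventional-fluorescence and
    photoactivated localization microscopy (PALM) experiments in living cells.
    Tracks diffraction-limited fluorescent clusters (e.g. dCas9-GFP-labelled
    telomeres) through an interleaved shutter sequence, links single-molecule
    localizations into traces, registers the single-molecule channel onto the
    conventional channel with a bead-calibrated third-order polynomial
    transform, classifies traces as bound, partially bound or unbound to a
    moving locus, subtracts locus motion to recover time-averaged
    super-resolved locus structure, and quantifies structure (convex-hull
    area, extension, radius of gyration, localization density) and mobility
    (time-averaged mean squared displacement, diffusion coefficients,
    log-normal mixture states, distribution overlap). Includes a synthetic
    experiment generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    mclust,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
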