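Package: beamext
Title: Spatial Extent Estimation for MEG Sources with Extended-Source
    Beamformers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Minimum-variance (SAM/LCMV-type) scalar beamformer with
    extended-source lead-field models for estimating the spatial extent of
    cortical sources in MEG. Provides a spherical-conductor forward model
    (Sarvas formula) for magnetometer and axial-gradiometer helmet arrays,
    disc-shaped and surface-following cortical patch source models, a
    synthetic folded-cortex mesh generator, a multi-epoch simulator with
    white and spatially coloured noise, pseudo-Z radius scans with fixed,
    optimised and surface-constrained position strategies, and the summary
    statistics used to characterise extent recovery under varying SNR,
    cortical curvature and co-registration error.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    stats,
    utils
Suggests:
    withr,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
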