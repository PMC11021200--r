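Package: clearvol
Title: Volumetric Quantification for Cleared-Tissue Light-Sheet Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying whole-body light-sheet microscopy volumes of
    cleared tissue: 3D connected-component labeling with physical-unit
    morphometry on anisotropic voxel grids, nearest-neighbor spatial statistics
    between object classes (e.g. tertiary lymphoid structures and metastases),
    organ-region density summaries, skeleton-based filament length and density
    estimation for nerve plexus networks, voxel colocalization ratios, and
    staining penetration-depth profiling. Includes a synthetic phantom
    generator with exact ground truth that emulates the acquisition geometry
    of whole-body scans, so every analysis stage can be validated without
    microscope data, and a reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
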