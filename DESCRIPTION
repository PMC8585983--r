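Package: veinstrain
Title: Strain Fields in Vessel Walls from Volumetric Photoacoustic Image Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes three-dimensional strain fields in vessel-like soft-tissue
    structures from series of volumetric photoacoustic images taken under
    increasing load (intraocular pressure). High-contrast feature voxels are
    detected in a near-zero-strain reference frame and tracked frame-to-frame
    by multi-window normalized cross-correlation with a consensus rejection
    rule; accepted points are decimated and meshed by Delaunay triangulation
    into constant-strain simplex elements; per-element deformation gradients
    yield logarithmic (true) strain tensors, nodal averages and
    area/volume-weighted average strains, which are fitted against pressure by
    logarithmic laws. A speckle phantom generator with analytically known
    deformation fields provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
SystemRequirements: fftw3
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
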