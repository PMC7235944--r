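Package: trabemorph
Title: Trabecular Bone Morphometry from 3D Micro-CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the standard micro-CT morphometric parameters of
    trabecular bone -- bone volume fraction (BV/TV), bone surface (BS),
    trabecular thickness (Tb.Th), trabecular separation (Tb.Sp) and degree
    of anisotropy (DA) -- from binary, isotropic-voxel 3D images. Exposes
    the implementation variants known to drive disagreement between
    analysis tools: voxel-count versus mesh-enclosed bone volume, inclusion
    or exclusion of artificial cut surfaces at the region-of-interest
    boundary, edge handling of the maximal-sphere local-thickness field,
    and the acquisition method (parallel test lines or projected
    triangulated surface) and eigenvalue normalisation of the mean
    intercept length fabric tensor. Includes a grayscale segmentation
    chain (Gaussian filter, single-level threshold, largest-component
    retention, morphological closing and opening), phantom generators with
    analytic ground truth, readers and writers for TIFF stacks, MetaImage
    and NIfTI volumes, and an agreement-analysis harness (pairwise percent
    differences, Bland-Altman limits of agreement, linear regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    tiff,
    jsonlite,
    stats,
    graphics,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
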