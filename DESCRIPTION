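Package: bgcnn
Title: Geodesic Convolutional Networks on the Sphere for Voxel-Wise
    Diffusion MRI Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rotation-invariant convolutional networks for signals on the
    unit sphere, built from three layers: a lifting layer that correlates
    the signal with a parallel-transported tangent-plane kernel at each of
    the discrete tangent rotations, a group-correlation layer over the
    cyclic rotation group of each tangent plane, and a max projection that
    collapses the rotation axis to produce features independent of the
    transport path and base point. The sphere is discretised by the twelve
    vertices of a regular icosahedron and directional measurements are
    interpolated onto tangent-plane sample points with a Watson kernel.
    Includes focal-loss training with analytic gradients, a synthetic
    rotation-classification benchmark generator, and NIfTI/FSL plumbing
    for single-shell diffusion-weighted MRI voxel classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    RNifti,
    withr,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
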