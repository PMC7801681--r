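Package: sdi3d
Title: Spatial Distribution Analysis of Finite-Sized Objects in Confined 3D Domains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for testing spatial-organization rules of finite-sized
    spherical objects (such as heterochromatin chromocenters) confined in
    bounded 3D domains (such as cell nuclei). Provides confined-domain
    geometry (analytic spheres and ellipsoids, watertight triangular meshes,
    voxel masks with anisotropic spacing), extraction of object patterns from
    labeled 3D images, six cumulative distance-distribution descriptors
    (empty-space F, nearest-neighbour G, pairwise H, boundary B, centre C and
    farthest-neighbour Z), conditional simulation of null and structured
    spatial models (completely random hard-sphere packing, orbital, maximal
    repulsion by Metropolis annealing, and border-biased placement), and the
    Spatial Distribution Index (SDI) goodness-of-fit test at the
    single-pattern and population levels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
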