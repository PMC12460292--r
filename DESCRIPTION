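Package: disctls
Title: Terrestrial Laser Scanning Disc Volume Pipeline and Agreement Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the volume of tree stem discs from terrestrial laser
    scanning (TLS) point clouds. Repairs the ground-contact occlusion of a
    scanned disc by projecting all points onto the minimum-Z plane, estimates
    oriented per-point normals by local quadratic-patch least squares with
    minimum-spanning-tree sign propagation, reconstructs a watertight triangle
    mesh by solving the Poisson equation for an indicator function on a regular
    grid (FFT) with marching-tetrahedra isosurface extraction, and integrates
    the enclosed volume with the divergence theorem. Includes a synthetic disc
    scan generator with known analytic volume (bark roughness, multi-station
    visibility, bottom occlusion, sensor noise) and a measurement-agreement
    suite (Bland-Altman limits of agreement, concordance correlation, gauge
    repeatability, Kruskal-Wallis and Mann-Whitney tests) for validating
    TLS volumes against water-displacement reference measurements.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
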