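Package: edenSat
Title: Modified Eden Growth Simulation and 3D Colony Morphology Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Stochastic lattice simulation of bacterial colony growth in
    confining matrices, where surface cells divide (Eden growth) and
    sufficiently exposed cells occasionally disperse by Gaussian jumps,
    seeding detached satellite colonies. Implements an exact Gillespie
    event loop on a 3D cubic lattice together with the matching 3D
    morphology pipeline (Otsu thresholding, minimum-volume filtering,
    connected-component labeling, per-object volume, center-of-mass,
    convexity and satellite statistics), a synthetic voxel-stack fixture
    generator with known ground truth, and parameter-sweep experiment
    drivers for jump rate and jump distance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
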