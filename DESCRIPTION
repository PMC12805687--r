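Package: follimetry
Title: 3D Morphometry of the Ovarian Follicle Reserve and Virtual Histology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the ovarian follicle reserve from labeled 3D
    micro-CT-scale volumes: oocyte instance extraction from binary masks
    (noise removal, vessel filtering, watershed separation of touching
    oocytes), cortex delineation by Euclidean distance from the surface
    epithelium, per-oocyte depth and fixed-radius neighbor counts, and
    volumetric oocyte density. Simulates virtual histological sectioning of
    a known oocyte population and applies a Schmidt/Abercrombie-type
    profile-count correction to evaluate when sparse 2D sampling
    approximates full-volume 3D counts. Includes a cluster point-process
    phantom generator that synthesizes cortical volumes with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
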