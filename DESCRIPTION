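Package: negcontrast
Title: Quantification of Negative-Contrast Intravital Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects unlabeled cells imaged as dark objects against a
    fluorescently labeled interstitium, as produced by intravital two-photon
    microscopy of bone marrow and lymph node after vascular or lymphatic
    tracer injection. Provides LUT inversion and contrast enhancement,
    marker-controlled watershed cell segmentation in 2D and 3D, a
    sphere-packing model linking 2D sections into 3D cell records, cell
    density and diameter censuses, anisotropic distance-to-vessel statistics
    with random-dot references, temporal standard-deviation motion maps,
    vessel segmentation/skeletonization with Hough segment selection, and
    digital line-scan (kymograph) blood-flow velocimetry with
    Radon-transform slope estimation. A synthetic phantom generator with
    complete ground truth makes every stage testable without experimental
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    graphics,
    grDevices,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
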