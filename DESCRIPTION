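Package: fibreholo
Title: Inline Holographic Microscopy Through Fiber Imaging Bundles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Processing pipeline for lensless inline holographic microscopy
    performed through coherent fiber imaging bundles. Removes the fiber-core
    mosaic by a precomputed Delaunay/barycentric interpolation calibration,
    combines holograms acquired under multiple laterally offset illumination
    fibers into a resolution-enhanced hologram, numerically refocuses by the
    angular spectrum method with a circular cosine edge window, and
    parameterizes the depth dependence of the inter-source hologram shifts so
    that enhancement calibrations can be pre-generated in a depth-indexed
    look-up table. Includes a synthetic forward simulator (quasi-hexagonal
    bundle sampling, USAF 1951 resolution targets, shifted-source holograms)
    so that every stage can be exercised and validated without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
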