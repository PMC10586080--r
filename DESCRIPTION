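Package: prestressr
Title: Intracellular Prestress and Modulus Mapping from AFM Force-Volume Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of atomic force microscopy (AFM) force-volume
    (spectrum-image) data on living cells. Fits each force-deformation
    curve with one of four contact-mechanics models (Hertz, Sneddon,
    cortical-shell-liquid-core, and a Hertzian sphere model augmented with
    a horizontal prestress term), while describing the effective probe tip
    radius as a linear function of local topographic gradients and
    indentation depth. The tip descriptors are optimized by a
    Markov-chain Monte Carlo search that minimizes the map-wide variance
    of per-curve fitting error, and competing models are ranked by
    held-out prediction error. Produces signed prestress maps
    (tensile/compressive), elastic modulus maps, depth-windowed
    (cortex versus nucleoskeleton) maps, radial profiles, and line-scan
    time-series statistics, plus a synthetic virtual-cell phantom
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
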