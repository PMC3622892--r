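Package: motimech
Title: Mechanical State Analysis of Intestinal Motility from Diameter and Pressure Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring active (neurogenic and myogenic) and passive
    mechanical states of intestinal circular muscle from paired spatiotemporal
    recordings of gut diameter (video or impedance) and intraluminal pressure
    (manometry). Builds and aligns composite diameter-pressure maps, analyses
    pressure-diameter orbits and their near-linear phases, classifies every
    sample into one of twelve mechanical states with a Gaussian-emission hidden
    Markov model, clusters the result into active-excitation and
    active-inhibition maps, fits Hill's force-velocity rectangular hyperbola to
    contraction episodes, converts impedance recordings to internal-diameter
    maps, and generates synthetic motility datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    png,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
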