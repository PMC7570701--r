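Package: aosizer
Title: Acoustic-Optical Fish Sizing from Echograms and Ventral Video
Version: 0.1.0
Authors@R: person("ICAR", "Analytics", email = "dev@example.org", role = c("aut", "cre"))
Description: Tools for sizing free-swimming fish by fusing a split-beam
    echosounder and a monocular ventral camera. Detects and characterizes
    fish traces in echograms (Otsu binarization, morphological cleanup,
    connected-component extraction, area/solidity and acoustic filters,
    swimming-tilt indicator), fits an eight-parameter deformable tuna
    silhouette model to video frames, establishes spatio-temporal
    correspondence between the two sensors, and converts image-plane
    measurements to metric snout-fork length and width via the pinhole
    camera model and a trimmed mean over tracked measurements. Includes a
    synthetic paired-scene generator with full ground truth so every stage
    is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
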