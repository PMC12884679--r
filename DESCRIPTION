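Package: retavr
Title: Retinal Vessel Segmentation, Artery/Vein Classification and
    Arteriovenous-Ratio Morphometry for Hypertensive Retinopathy
Version: 0.1.0
Authors@R:
    person("retavr", "developers", email = "retavr@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of colour fundus photographs for
    hypertensive retinopathy screening: green-channel and CLAHE
    preprocessing, a residual U-Net vessel segmenter trained with binary
    cross-entropy, a graph convolutional artery/vein classifier built on
    an 8-connected vessel-pixel graph, calibre measurement of the major
    arterioles and venules around the optic disc, Parr-Hubbard central
    retinal artery/vein equivalents (CRAE/CRVE), the arteriovenous ratio
    (AVR), and an AVR-based retinopathy grade.  A synthetic fundus
    generator with known vessel trees, widths and calibres makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
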