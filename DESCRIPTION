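Package: icscore3d
Title: 3D Quantification of PD-L1 Immune-Cell Scores in Cleared-Tissue
    Fluorescence Z-Stacks
Version: 0.1.0
Authors@R:
    person("icscore3d", "Developers", email = "icscore3d@example.org",
           role = c("aut", "cre"))
Description: Computer-assisted quantification of PD-L1 expression on
    tumor-infiltrating immune cells in multichannel fluorescence z-stacks
    of optically cleared tumor tissue. Provides two-stage tumor/immune
    semantic segmentation (a trainable pixel classifier plus a
    deterministic threshold-and-morphology baseline), per-layer SP142-style
    immune-cell (IC) scoring with the 1% clinical cutoff, depth-profile
    heterogeneity analysis (threshold crossing, pattern classes, 3D
    averages), 2D-versus-3D concordance statistics, pseudo-H&E/IHC
    rendering, and a seeded synthetic tissue-phantom generator with exact
    ground truth so the whole pipeline is testable end-to-end without any
    imaging data. Includes a minimal multi-page TIFF reader/writer for
    stacks, masks and overlays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
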