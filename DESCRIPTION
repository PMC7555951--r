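Package: fociTrack
Title: Segmentation, Tracking and Mobility Analysis of DNA Damage Foci in
    Time-Lapse Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies DNA double-strand-break repair foci (such as 53BP1
    accumulations) in live-cell fluorescence time-lapse stacks and fixed-cell
    two-channel images. Provides adaptive per-frame intensity thresholding
    calibrated against a manually chosen threshold, watershed separation of
    touching foci, rigid-body stack stabilization, gap-free nearest-neighbour
    linking of focus centers of mass into tracks, mean-squared-displacement
    and apparent-diffusion-coefficient estimation, focus intensity and area
    time series, kernel-density distribution summaries, and two-channel
    nested-focus colocalization scoring. Includes a seeded synthetic
    time-lapse generator with full ground truth so the whole pipeline can be
    validated without real microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
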