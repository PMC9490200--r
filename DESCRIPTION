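Package: scfq
Title: Single-Cell Fluorescence Quantification for Monolayer Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies fluorescent cell populations in two-channel
    microscopy images of cell monolayers. Cells are detected from a
    nucleus-stain channel, segmented by a nuclei-seeded watershed using the
    intrinsic autofluorescence of the cell bodies to delimit the covered
    area, and the per-cell marker fluorescence is measured on a log10 scale
    after automatic background correction. The log10 intensity histogram is
    split into non-fluorescent and fluorescent populations by an offset
    cutoff, yielding the fluorescent fraction per image (e.g. transfection
    or infection efficiency). Includes recursive batch processing of image
    folders, a ground-truthed synthetic monolayer image generator for
    validation, and Langmuir-type dose-response fitting to recover IC50
    values with bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
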