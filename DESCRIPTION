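Package: retinacomm
Title: Intercellular Communication Analysis for Retinal Ganglion Cell Survival
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Ligand-receptor interaction analysis for multi-cell-type
    single-cell expression data, built around the signalling that supports
    retinal ganglion cell (RGC) survival after optic nerve injury. Provides
    quality-control filtering of gene-by-cell count matrices, marker-based
    cell type assignment, loop-aware ligand-receptor interaction scoring
    across time points, a differential interaction statistic contrasting
    high- and low-survival receiver subclasses, trajectory dynamics and
    preset/induced classification, survival-normalized subclass composition
    analysis, RNAscope dot quantification from intensity images, and a
    fully labelled synthetic-atlas generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    png,
    yaml
Suggests: testthat (>= 3.0.0), tiff, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
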