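Package: cellseg
Title: Contour-Expansion Segmentation of Cells in Negative Phase Contrast Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Automated segmentation of cultured cells in negative phase
    contrast microscopy images. Cells appear as bright convex intensity
    domes on a darker background, with brightness approximately linear in
    optical thickness. The package seeds an edge-based parametric active
    contour (snake) with the boundary of a global threshold mask and
    expands it outward, driven by the intensity gradient, to the cell
    boundary. Clustered cells are detected and split by regional maxima
    of the smoothed intensity, with per-cell contour initialization by
    nearest-peak partition of the mask. Includes a distance-transform
    watershed and a two-phase piecewise-constant active contour as
    comparison baselines, a physics-grounded synthetic phantom generator
    with ground truth, and segmentation-error scoring (oversegmentation,
    undersegmentation, over-detection).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
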