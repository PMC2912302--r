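Package: somavol
Title: Soma Volume Quantification for Bipolar Cells from Scanning Probe Height Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates the cell soma of a bipolar cell (such as an
    oligodendrocyte precursor cell) from its processes in topographic height
    maps obtained by scanning probe microscopy, and quantifies the soma
    volume. Implements a boundary delimitation algorithm (BDA) that locates
    a nucleus proxy as the centroid of the area above a relative height
    threshold, estimates the heading direction of the cell by arc-length
    minimization, rotates and re-interpolates the height map onto a
    heading-aligned lattice, delimits the soma line-by-line with polynomial
    contour fits, and integrates the enclosed volume with a frontal/rear
    split. Includes a half-ellipsoid phantom generator with attachable
    process-like extensions, the parameter sweeps used to validate the
    method, and a height-threshold comparator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
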