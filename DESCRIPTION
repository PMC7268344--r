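Package: colonyprof
Title: Normalized Spatial Fluorescence Profiles of Bacterial Colonies from
    Confocal Z-Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated extraction of statistically comparable three-dimensional
    fluorescence spatial profiles from confocal laser scanning microscopy
    (CSLM) Z-stacks of quasi-circular bacterial colonies. Colonies are detected
    on a sum projection by mean-based thresholding, connected-component
    labeling and two shape filters; each kept colony's axial (XY) projection
    and diametric (XZ) cross-section are aligned by principal-axis rotation
    and mapped onto a fixed dimensionless reference frame by similarity
    transforms; intensities are interpolated onto reference grids with a
    Clough-Tocher C1 cubic scheme on a Delaunay triangulation; and
    replicate-averaged profiles (mean, median, coefficient of variation) are
    computed with raw, control-based or min-max intensity normalization. A
    synthetic-colony generator produces ground-truth fixtures for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    interp,
    tiff,
    png,
    xml2,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
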