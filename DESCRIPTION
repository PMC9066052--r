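Package: mitoez
Title: Quantitative Analysis of the Mitotic ER Exclusion Zone and Ensheathed Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Image-analysis pipeline for 4D fluorescence microscopy of mitotic
    cells in which the endoplasmic reticulum (ER) is excluded from an
    ellipsoid zone around the spindle. Provides a synthetic scene generator
    with exhaustive ground truth; 3D segmentation of ER, cell, exclusion zone
    and chromosome objects on anisotropic voxel grids; an exclusion-zone
    distance-ratio statistic locating kinetochores relative to the ER
    boundary on a log2 scale; 4D chromosome tracking with congression and
    anaphase-onset detection and chromosome-to-plate fluorescence ratios;
    derivative-based ER-clearance detection with a random-occurrence null;
    3D puncta colocalization with a nearest-neighbour attachment criterion;
    and the mitotic timing, fate and survival statistics layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    pracma,
    stats,
    survival,
    tiff,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
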