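Package: bodyscan
Title: Two-View Depth-Camera Body Volume and Fat Mass Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Densitometric body-composition analysis from a pair of opposed
    infrared depth cameras. Renders synthetic scenes of body phantoms with
    known volume, segments the body silhouette from infrared frames, fuses
    silhouette and depth into masked depth images, back-projects them to
    point clouds, registers the two views with iterative closest points,
    reconstructs a watertight triangle mesh with a Poisson-style implicit
    surface solve, and computes body volume from the mesh. A densitometry
    layer converts volumes to body density, percent fat (Siri equation) and
    fat mass via a published regression equation, with replicate-selection
    and calibration rules; a concordance layer provides intraclass
    correlation, Bland-Altman agreement, coefficient of variation and
    best-subsets regression used to validate such systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    EBImage,
    png,
    yaml,
    jsonlite,
    igraph,
    Matrix,
    tibble,
    dplyr,
    readr,
    rlang,
    ggplot2,
    generics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
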