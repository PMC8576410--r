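Package: vtsubstrate
Title: Structural Substrate Analysis of Ventricular Tachycardia from
    LGE-CMR and Electroanatomic Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising the myocardial substrate of
    re-entrant ventricular tachycardia from late gadolinium enhancement
    cardiovascular magnetic resonance (LGE-CMR) together with
    electroanatomic mapping data.  Provides maximum-referenced signal
    intensity thresholding of scar and heterogeneous (border zone)
    tissue, Laplace-equation wall thickness and streamline transmurality,
    radial basis function thickness-gradient fields and distance maps on
    the endocardial surface, landmark plus iterative-closest-point
    co-registration of mapping points to the imaging mesh, detection and
    quantification of conduction-block lines from activation maps,
    diastolic-phase classification, and the accompanying nonparametric
    statistical battery.  A synthetic phantom generator with full ground
    truth (wall geometries, scar patches of controlled transmurality,
    displaced mapping frames, two-wavefront activation maps) supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
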