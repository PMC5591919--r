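Package: cardiokin
Title: Kinematic and Dynamic Analysis of Beating Cardiac Syncytia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Video-based analysis of spontaneously beating cardiac syncytia
    under beta-adrenergic (isoproterenol) and 75 Hz pulsed electromagnetic
    field stimulation. Provides a synthetic-data generator for marker
    trajectories and rendered microscopy stacks with analytic ground truth,
    subpixel normalized cross-correlation spot tracking on an orthogonal
    marker grid, beat segmentation with per-beat contraction displacement,
    velocity and acceleration metrics, one-way ANOVA with Fisher least
    significant difference confidence intervals, Biot-Savart dosimetry of a
    coaxial solenoid-pair bioreactor, and quantification of synthetic
    sarcomeric-myosin immunofluorescence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    Rcpp,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    yaml,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
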