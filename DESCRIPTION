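Package: oscillung
Title: Forced-Oscillation PEEP Titration with a Recruiting Lung Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis of forced oscillation technique (FOT) measurements
    acquired during incremental/decremental PEEP titration under
    volume-controlled ventilation. Provides least-squares estimation of
    respiratory input impedance at the oscillation frequency, oscillatory
    elastance at end-expiration and end-inspiration extracted from
    ventilator holds, equation-of-motion and intra-tidal (SLICE) mechanics,
    CT aeration-compartment accounting from Hounsfield-unit voxel tables,
    and open-lung PEEP selection on the decremental limb. A deterministic
    multi-unit lung simulator with hysteretic alveolar
    recruitment/derecruitment and strain-stiffening pressure-volume
    behaviour generates matched waveform records and CT phantoms with
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
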