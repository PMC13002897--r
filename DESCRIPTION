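Package: probeseize
Title: Optogenetic Seizure-Suppression Analysis for Multifunctional Neural Probes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for multimodal silicon neural-probe experiments
    combining extracellular recording, on-shank photostimulation and
    microfluidic drug delivery. Implements the signal-conditioning chain
    (common average referencing, zero-phase bandpass filtering,
    photostimulation-artifact blanking), pulse-locked spiking analysis
    (threshold detection, unit-quality gating, raster fraction-in-pulse,
    baseline versus stimulated firing rates, optical-power dependence,
    emitter-proximity selectivity), and seizure-suppression statistics
    (neural activity power, suppression ratio, electrode-by-emitter SR
    matrices, fraction of positive suppression ratios, one-tailed
    Mann-Whitney pre/during/post tests, onset detection). A seeded synthetic
    recording generator emulates the probe geometry, photostimulation
    protocols and chemically induced epileptiform dynamics so that every
    stage is testable against ground truth without animal data. Device
    quality-control estimators (optical transmission, microfluidic flow
    resistance, electrode impedance summaries) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
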