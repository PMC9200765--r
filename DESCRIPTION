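Package: loomattend
Title: Escape Decisions and Looming-Sensitive Neuronal Responses Under
    Single and Paired Threats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how animals resolve simultaneous looming
    threats: kinematics of simulated approaching objects (angular subtense,
    expansion rate, time to collision, Weber contrast, display
    linearisation), circular statistics for escape directions (Rayleigh
    test, Rao-type dispersion homogeneity, multimodal-to-unimodal angle
    transforms, sector classification, bootstrap intervals for circular
    means), Gaussian-kernel spike-rate estimation with spike-count
    conservation and threshold-based response-onset detection, and
    decision procedures that discriminate selective from divided attention
    in behaviour and select-stronger from sum or average integration in
    looming-sensitive neurons. Includes seeded generators for synthetic
    escape-trial tables (von Mises mixtures with body-orientation and
    contrast biases) and inhomogeneous-Poisson spike trains so the whole
    pipeline is testable without external recordings.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
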