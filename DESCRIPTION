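Package: quantus
Title: Quantitative Ultrasound Simulation, Estimation and Breast Lesion
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale quantitative ultrasound (QUS) workbench for breast
    tissue characterization.  Generates breast-tissue-mimicking acoustic
    phantoms, simulates multi-angle plane-wave radio-frequency (RF) channel
    data with a point-scatterer forward model, reconstructs attenuation
    coefficient (AC), speed of sound (SoS), effective scatterer diameter
    (ESD) and effective scatterer concentration (ESC) maps by classical
    spectral estimators and by a conditional encoder-decoder neural
    network, and classifies lesions as benign or malignant with a QUS
    logistic model together with the accompanying statistical battery
    (Mann-Whitney, ROC/AUC with bootstrap confidence intervals,
    Clopper-Pearson intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
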