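Package: retquant
Title: Quantification of Retinal SD-OCT Biomarkers and Prediction of
    Disease Activity
Version: 0.1.0
Authors@R:
    person("retquant", "developers", email = "retquant@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for spectral-domain optical coherence
    tomography (SD-OCT) B-scans of neovascular age-related macular
    degeneration: clip-based convolutional detection of the ellipsoid zone
    (EZ) and external limiting membrane (ELM), fully convolutional
    segmentation of intraretinal fluid (IRF), subretinal fluid (SRF),
    subretinal hyperreflective material (SHRM) and pigment epithelium
    detachment (PED), quantitative biomarker extraction (length rates,
    areas, maximum diameters, mean reflectivity), segmentation metrics
    with bootstrap confidence intervals, and a longitudinal random-forest
    model predicting three-class one-year disease activity.  Ships a
    seeded synthetic B-scan generator with analytic ground truth so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Depends: R (>= 4.1)
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
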