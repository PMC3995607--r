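Package: petrp
Title: Pre-Treatment FDG-PET Lung Biomarkers and Radiation Pneumonitis Risk Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to extract percentile standard-uptake-value (SUV) and
    Hounsfield-unit biomarkers from thoracic PET/CT, compute lung
    dose-volume metrics from radiotherapy dose grids, and relate both to
    symptomatic radiation pneumonitis with a full outcome-analysis
    battery: association tests, univariate and backward-AIC multiple
    logistic regression with Holm adjustment and Nagelkerke R-squared,
    ROC analysis with DeLong confidence intervals and the Youden
    cutpoint, depth-limited recursive partitioning, Kaplan-Meier tercile
    curves, Cox proportional-hazards regression, and Bland-Altman
    inter-reader limits of agreement.  Includes generators for thoracic
    phantoms with known lung-SUV distributions and simulated patient
    cohorts, so the whole pipeline runs end-to-end without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    Rcpp,
    RNifti,
    jsonlite,
    survival,
    pROC,
    rpart
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
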