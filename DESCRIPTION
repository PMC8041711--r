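Package: autobsuv
Title: Automated Image-Based Blood SUV Determination in Whole-Body FDG-PET/CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated determination of the arterial blood standardized
    uptake value (BSUV) from paired whole-body FDG-PET/CT volumes, for use in
    standardized uptake ratio (SUR) quantification. Provides a synthetic
    thoracic PET/CT phantom simulator with rule-based ground-truth labels of
    the usable aortic-lumen core, PET/CT preprocessing to a common normalized
    slice stack, a two-channel 2-D U-Net implemented natively with
    Rcpp/RcppArmadillo, RMSprop training under logistic loss with non-rigid
    warp augmentation and a blood-SUV-error validation metric for model
    selection, and an evaluation protocol reporting relative BSUV deviations,
    Dice coefficients and delineation failures.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), yaml, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
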