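Package: ccscat
Title: Continuous Item Pool Calibration for Computerized Adaptive Testing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building a calibrated item pool for computerized
    adaptive testing (CAT) across operational test cycles with the
    continuous calibration strategy (CCS). Implements the two-parameter
    logistic (2PL) measurement model with marginal maximum likelihood
    (MML-EM) item calibration, maximum a posteriori ability estimation,
    maximum-information adaptive item selection, common-item equating via
    moment (mean/mean, mean/sigma) and characteristic-curve (Haebara,
    Stocking-Lord) scale transformations, Lord-type chi-squared item
    parameter drift detection with iterative purification, fixed
    common-item parameter (FCIP) calibration, and a full-factorial Monte
    Carlo driver evaluating equating setups by conditional mean squared
    error of item parameters, equating feasibility, drift rates, and the
    error of the transformation constants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, MASS, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
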