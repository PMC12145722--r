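Package: subfracdose
Title: Simulation and Dose Accumulation for Sub-Fractionated MR-Guided
    Prostate Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end simulation of a tight-margin sub-fractionation
    workflow for MR-Linac prostate radiotherapy. Generates synthetic pelvic
    anatomy with intrafraction and interfraction prostate motion, estimates
    residual shifts with a variational deformable image registration engine
    (including a contour-guided variant and a median-of-repeats robustness
    wrapper), applies a traffic-light margin-adaptation protocol, builds
    idealized per-subfraction dose plans, accumulates warped dose maps
    within and across fractions, evaluates dose-volume-histogram
    constraints, and compares delivered treatments against counterfactual
    re-planning with the original tight margins.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
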