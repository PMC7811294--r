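Package: glnamm
Title: Glutamine/Ammonium Exchange Dynamics of Cancer Cells and
    Cancer-Associated Fibroblasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary-differential-equation models of the bidirectional
    glutamine/ammonium metabolic exchange between breast cancer cells and
    cancer-associated fibroblasts in monoculture and coculture, including a
    stress-factor extension of the merged coculture model.  Provides an
    adaptive Runge-Kutta simulator, least-squares parameter estimation by
    Nelder-Mead over log-transformed parameters, parametric-bootstrap
    percentile confidence intervals, sensitivity ranking by normalized
    confidence-interval width, a synthetic time-course data generator
    mirroring the dosing design of the underlying experiments, and scenario
    suites (monoculture dose panels, merged and stress cocultures, and a
    fibroblast renormalization counterfactual).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    deSolve,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
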