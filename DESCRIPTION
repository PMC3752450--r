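Package: epiflux
Title: Quantitative Modelling of Ion Transport in Human Nasal Epithelium
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Biophysical model of Na+, K+ and Cl- transport across a monolayer
    of human nasal epithelial cells. Channel currents follow the
    Goldman-Hodgkin-Katz flux equation, active transport uses saturating
    Na+/K+-ATPase and Na+-K+-2Cl- cotransporter kinetics, and apical,
    basolateral and paracellular currents are coupled through an equivalent
    electrical circuit that determines membrane and trans-epithelial
    potentials in the open-circuit configuration. The package solves the
    model to steady state, simulates amiloride and low-chloride perturbation
    protocols (including the clinical nasal potential-difference test),
    estimates transport parameters by bound-constrained least squares,
    filters Monte Carlo parameter ensembles against physiological bounds to
    obtain non-CF and cystic fibrosis (CF) parameter populations, and
    quantifies parameter influence on bioelectric read-outs by multiple
    linear regression.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
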