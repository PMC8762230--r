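Package: voripk
Title: Joint Population Pharmacokinetics of Voriconazole and Its N-Oxide
    Metabolite
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint parent-metabolite population pharmacokinetic modelling of
    oral voriconazole and voriconazole N-oxide in adults, with mixed linear
    and saturable (Michaelis-Menten) elimination and metabolite-mediated
    auto-inhibition of the parent clearance. Provides the structural
    one-compartment parent plus one-compartment metabolite model with a
    compiled ODE integrator, FOCE-style nonlinear mixed-effects estimation
    with CYP2C19 phenotype covariate modelling and stepwise covariate
    selection, empirical Bayes individual exposure metrics, model
    qualification by nonparametric bootstrap, visual predictive check and
    conditional weighted residuals, Monte Carlo dose-optimization
    (probability of target attainment) simulation across CYP2C19
    metabolizer phenotypes, a study-design emulator for synthetic cohorts,
    and NONMEM-style dataset input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
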