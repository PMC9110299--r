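Package: fmclock
Title: Fluctuating Methylation Clocks for Stem Cell Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers stem cell niche dynamics from fluctuating CpG (fCpG)
    methylation measured on bulk methylation arrays. Implements a
    master-equation hidden-Markov model of methylation within a well-mixed
    stem cell niche, a beta-mixture measurement-error model for array beta
    values, and fully Bayesian inference of the stem cell number S,
    replacement rate lambda and (de)methylation rates mu and gamma via
    nested sampling with evidence-based model averaging over S. Includes
    exact Gillespie simulators of the niche (well-mixed and ring
    geometries) for validation and synthetic data generation, an fCpG
    locus selection pipeline for array probe manifests, and a
    blood-clonality variance module with a simple hematopoiesis
    clonal-expansion simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
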