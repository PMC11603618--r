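Package: crystalfit
Title: Force-Field Parameter Estimation for Molecular Crystals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bilevel estimation of Buckingham repulsion/dispersion parameters
    for rigid-molecule crystal structure prediction force fields. Provides a
    point-charge Ewald plus exp-6 lattice-energy model with analytic first
    derivatives with respect to the rigid-body degrees of freedom and the
    potential parameters, a two-stage lattice-energy minimizer under space
    group symmetry, geometry and energy residuals against reference crystal
    structures, implicit-function sensitivities of the optimized structures
    with respect to the parameters, and a robust multistart outer optimizer
    with dynamic starting points, structure removal and Sobol' sampling.
    Includes a synthetic-data generator producing reference training sets
    from known parameters, SHELX .res input/output, and a manifest format
    for charges, atom types and reference energies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
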