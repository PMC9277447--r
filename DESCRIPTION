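Package: tcaflux
Title: Steady-State 13C-Isotopomer Modeling and Flux Estimation for the
    TCA Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates steady-state carbon-13 labeling of TCA-cycle
    intermediates under [U-13C]glucose tracing, predicts the glutamate and
    lactate 13C-NMR multiplet patterns (singlet, doublet, triplet and
    quartet area fractions) that report on relative pathway fluxes, and
    estimates pyruvate dehydrogenase, pyruvate carboxylase anaplerosis,
    pyruvate-kinase cycling and succinyl-CoA anaplerosis fluxes (all
    referenced to a citrate synthase flux of 1) from observed multiplet
    ratio tables by bounded multi-start nonlinear least squares with
    bootstrap uncertainty and information-criterion model comparison.
    Includes a replicate-structured synthetic-data generator, a Monte
    Carlo lineage-tracing oracle for the fixed-point solver, and a
    Lorentzian line-shape renderer and fitter for multiplet
    quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    pracma,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
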