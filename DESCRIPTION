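Package: denopk
Title: Population Pharmacokinetics of Denosumab with Parallel Linear and
    Michaelis-Menten Elimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Population pharmacokinetic (popPK) meta-analysis toolkit for
    subcutaneous denosumab. Implements a one-compartment structural model
    with first-order absorption and parallel linear plus saturable
    (Michaelis-Menten, target-mediated) elimination, body-weight and study
    covariates, log-normal inter-individual variability and proportional
    residual error. Provides NONMEM-style dataset input/output with
    below-quantification-limit handling, virtual phase I / phase III trial
    simulation, approximate marginal-likelihood (Laplace, FOCE-like)
    estimation with empirical Bayes estimates, shrinkage and
    likelihood-ratio covariate tests, goodness-of-fit and visual predictive
    checks, model-based bioequivalence on derived exposure metrics (Cmax,
    AUC0-tau, AUC0-inf) against the 80-125% margin, and virtual-trial
    simulation for dose extrapolation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
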