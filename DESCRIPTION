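Package: pops
Title: Probability of Pharmacological Success by Nested Monte Carlo Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates the probability of pharmacological success (PoPS) for
    early-stage drug candidates: the probability that pre-specified benefit
    and risk criteria are jointly met in a virtual patient population, given
    uncertainty in model parameters, translation factors and the success
    criteria themselves.  A nested Monte Carlo engine draws uncertainty
    replicates (virtual trials) in an outer loop and between-subject
    variability in an inner loop, evaluates thresholded-proportion criteria
    per replicate, and reports PoPS-versus-dose curves with predictive bands.
    Includes a library of translational PKPD structural models (one-compartment
    absorption, turnover/indirect-response, target-mediated drug disposition),
    a probability-of-target-attainment workflow for anti-infectives (MIC
    distribution fitting, AUC:MIC index construction, benchmark overlap), and
    fully synthetic, documented case-study configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
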