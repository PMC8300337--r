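Package: doxypk
Title: Population Pharmacokinetics of Multiple-Dose Oral Doxycycline in Donkeys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Nonlinear mixed-effects analysis of serum doxycycline
    concentrations after repeated intragastric dosing in donkeys. Implements
    a one-compartment first-order-absorption structural model under
    multiple-dose superposition, lognormal inter-individual variability,
    stochastic approximation EM (SAEM) estimation with importance-sampling
    log-likelihood, BIC, Louis-identity standard errors and posterior
    parameter correlations, goodness-of-fit diagnostics (IWRES, NPDE,
    Monte-Carlo prediction bands), post-hoc individual parameter estimates,
    descriptive serum and tissue summaries, a study-design-faithful
    synthetic-data generator, and a NONMEM-style dataset reader/writer with
    a scripted end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
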