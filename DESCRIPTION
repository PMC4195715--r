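Package: t2dcohort
Title: Deterministic Cohort Simulation and External Validation of Type 2
    Diabetes Outcome Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic annual-cycle cohort (Markov) model of type 2
    diabetes complications with pluggable macrovascular risk-equation
    families (UKPDS-OM1-style Weibull, UKPDS-OM2-style Gompertz/logistic,
    and NDR-style five-year risk equations), progressive microvascular
    state tracks (retinopathy, nephropathy, neuropathy), and an external
    validation pipeline that simulates published study cohorts, extracts
    cumulative-incidence endpoints, and quantifies concordance between
    predicted and observed outcomes by cluster-robust linear regression.
    Includes a synthetic-fixture generator so the whole pipeline is
    testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
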