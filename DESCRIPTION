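Package: atsim
Title: Agent-Based Simulation of Two-Drug Adaptive Cancer Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid agent-based model of tumor evolution under two-drug
    treatment. Four cell phenotypes (doubly sensitive, singly resistant to
    either drug, doubly resistant) live on a 2-D lattice, divide, die, mutate
    and compete for space, while two drug concentration fields are dosed
    uniformly, decay and diffuse via an alternating direction implicit (ADI)
    solver. Six treatment controllers (standard maximum-tolerated-dose
    therapy, dose-modulation cocktail and ping-pong variants, and fixed-dose
    skipping/intermittent variants) adjust dosing from noisy burden
    measurements. A replicate harness scores time to progression and compares
    treatment arms with Kaplan-Meier curves and Cox proportional-hazards
    regression.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    survival,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
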