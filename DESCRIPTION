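Package: dddfba
Title: Demand-Directed Dynamic Flux Balance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Demand-directed dynamic flux balance analysis (dddFBA) couples a
    constraint-based metabolic model to explicit mRNA and protein balance
    equations for selected enzymes. Transcription of an enzyme is switched on
    whenever the parsimonious flux through its reaction approaches the current
    enzyme-capacity bound, and simulated protein levels in turn impose
    kcat-scaled upper bounds on the fluxes. The package provides the dynamic
    FBA loop (growth maximisation, flux minimisation, culture integration,
    bound recalculation), flux variability analysis, estimation of
    transcription parameters from RPKM time courses with a Heaviside-activated
    mRNA model, a flux-versus-expression correlation pipeline, and a
    synthetic-data module with a small aerobic/anaerobic toy network for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    quadprog,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
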