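Package: dipsim
Title: Hybrid Simulation of Diabetes in Pregnancy for Policy Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale hybrid simulator of diabetes in pregnancy (DIP)
    combining a system-dynamics ageing chain for the aggregate female
    population, individually tracked agents "budded" from the aggregate
    structure, and discrete-event screening and treatment pathways.
    Agents carry a latent metabolic model (insulin sensitivity, beta-cell
    function, cumulative dysglycemia exposure) coupled to continuous BMI
    dynamics, so that screening policies, diagnostic-threshold changes and
    pre-, inter- and during-pregnancy interventions can be compared against
    a common baseline with common random numbers. Includes calibration of
    free parameters to historic incidence anchors, one-at-a-time
    sensitivity analysis, a model-readiness report, and per-agent "life
    story" narrative rendering from the simulation event log.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    data.table,
    jsonlite,
    lhs,
    Rcpp,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
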