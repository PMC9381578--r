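Package: optoculture
Title: Host-Aware Simulation and Optogenetic Feedback Control of Bacterial
    Co-Cultures
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: In-silico stack for compositional control of a two-strain
    Escherichia coli co-culture via optogenetic modulation of antibiotic
    resistance. Implements a host-aware ODE framework that couples synthetic
    gene-circuit dynamics to proteome-partition bacterial growth laws, a
    concrete model of a photophilic strain (light-activated split-T7
    polymerase driving chloramphenicol acetyltransferase), the replicator
    equation for co-culture composition, a discrete PID controller with
    back-calculation anti-windup, a computational gain screen, nonlinear
    least-squares model fitting to dynamic upshift/downshift data, and a
    virtual continuous-culture platform (turbidostat dilution logic,
    growth-rate estimation from optical density, flow-cytometry sampling with
    threshold gating) that closes the feedback loop without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
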