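Package: tsp1net
Title: Simulation of Hypoxia- and TGF-beta-Driven Thrombospondin-1 Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compartmental reaction-network simulator of intracellular
    thrombospondin-1 (TSP-1) regulation in endothelial cells. The shipped
    network couples oxygen sensing through PHD/FIH-mediated hydroxylation of
    HIF-1alpha and HIF-2alpha, microRNA biogenesis and RISC-mediated mRNA
    repression (let-7 and miR-18a), TGF-beta receptor trafficking with
    SMAD activation and SMAD7 negative feedback, and calcium/calmodulin/
    calcineurin-driven NFATc1 activation, all converging on a multiplicative
    TSP-1 transcription function. The package provides stiff ODE simulation
    protocols (hypoxia shifts, TGF-beta dosing, cycloheximide, therapeutic
    interventions), steady-state initialization, fold-change/AUC readouts and
    dose scans, Latin-hypercube/PRCC global sensitivity analysis, and
    normalized least-squares calibration with synthetic-dataset generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    lhs,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
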