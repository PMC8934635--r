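Package: plectodimer
Title: Mesoscale Simulation and Analysis of Supercoiled DNA with Thymine-Dimer Defects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale Monte Carlo simulator for a discrete twist-storing
    DNA chain under magnetic-tweezer boundary conditions (fixed handle,
    pulling force, imposed turns, repulsion planes), with a coarse-grained
    model of the thymine dimer (cyclobutane pyrimidine dimer) photoproduct:
    an increased roll angle, weakened base pairing and enhanced stacking at
    the lesion. Includes trajectory analysis of supercoiled DNA: twist,
    writhe and linking-number bookkeeping, plectoneme detection and pinning
    statistics, denaturation-bubble and tip-bubble classification,
    force-torsion state diagrams, bend-angle measurement, equilibration
    policies and denaturation probabilities. Readers and writers for the
    oxDNA topology/configuration dialects let the analysis layer run on
    external coarse-grained trajectories, and deterministic synthetic
    fixture generators (ideal helices, planted plectonemes, bubbles, kinks
    and tip random walks) provide ground-truth-labelled test inputs.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
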