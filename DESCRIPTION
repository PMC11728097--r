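Package: hippotrial
Title: In Silico Randomized Trials of Memantine and Deep Brain Stimulation
    in a Hippocampal Network Model of Alzheimer's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A DG-CA3-CA1 hippocampal spiking-network simulator with
    shift-register AMPA/NMDA synapse dynamics, voltage-dependent Mg2+ block
    gating, long-term potentiation, and an excitotoxicity drive. Builds
    cohorts of virtual Alzheimer's disease patients by graded loss of
    entorhinal (EC2) projections, applies mechanistic therapy operators
    (memantine as an NMDA unblock-threshold shift, 40 Hz perforant-path deep
    brain stimulation, and their combination), and runs four-arm randomized
    in silico trials whose endpoints are control-normalized spike counts in
    DG, CA3 and CA1, analyzed with one-way ANOVA and Tukey HSD post hoc
    tests.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
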