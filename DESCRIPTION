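Package: fluorovolt
Title: Simulation and Analysis of Voltage-Clamp Fluorometry Recordings
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing voltage-clamp fluorometry (VCF) sweep
    recordings from ligand- and voltage-gated ion channels, together with a
    generative simulator for validating every stage without experimental data.
    Implements linear photobleaching estimation and compensation (additive and
    multiplicative modes), baseline normalisation and per-step delta-F/F
    computation, decomposition of the fluorescence step response into an
    instantaneous electrochromic (fast) component and a gating-coupled (slow)
    component, F-V curve construction with linearity classification,
    tail-current G-V analysis with two-state Boltzmann fitting,
    mono-exponential activation kinetics, and the group comparisons commonly
    used in VCF studies. A preset registry reproduces published recording
    conditions for P2X2 receptor and Ci-VSP constructs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
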