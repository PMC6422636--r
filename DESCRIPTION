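Package: circuitmap
Title: Statistical Analysis of Optogenetic Circuit Mapping and Paired-Recording Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring synaptic connectivity from optogenetic
    photostimulation mapping and paired intracellular recordings in cortical
    circuits. Implements per-site detection of evoked synaptic input from
    event trains (Poisson null with Benjamini-Hochberg FDR control), a
    fine-timescale interval-jitter synchrony test for common presynaptic
    input to simultaneously recorded cells, hierarchical Monte Carlo
    permutation tests for connection-rate differences, charge-map
    construction and laminar alignment, intrinsic-electrophysiology feature
    extraction (threshold, spike width, rheobase, adaptation index) with a
    two-feature cell-type classifier, and in vivo unit modulation analysis
    with Poisson regression. A synthetic-data generator produces event
    trains, current-step sweeps, connectivity tallies and in vivo spike
    records from known ground-truth circuits for validation of the entire
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
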