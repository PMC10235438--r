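Package: patchkit
Title: Patch-Clamp, Calcium-Imaging and Compartment-Fraction Analysis for
    Cultured Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Feature extraction and statistics for cellular neurophysiology
    experiments on cultured neurons. Detects action potentials by a dV/dt
    threshold criterion and measures spike waveform features (threshold,
    amplitude, half width, afterhyperpolarization), rheobase, input/output
    curves and the accommodation index from current-clamp step families;
    estimates passive membrane properties and Kir, HCN and A-type slope
    conductances from voltage-clamp families; detects and summarizes
    miniature excitatory postsynaptic currents with a summation-exclusion
    rule; computes dF/F0 and detects synchronous population calcium
    transients against a bicuculline reference; quantifies nuclear-to-
    cytoplasmic fluorescence ratios; estimates nuclear/cytoplasmic RNA
    proportions from qPCR Ct values with arcsine-transformed summaries; and
    reports normality-gated group statistics with the multiple-comparison
    adjustments used in the field. A biophysical synthetic-data generator
    with recorded ground truth makes every stage testable without raw
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    zoo,
    pracma,
    signal,
    car,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
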