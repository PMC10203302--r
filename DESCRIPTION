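Package: conformerge
Title: Integrative Gas-Phase Peptide Structure Determination from FRET,
    Ion Mobility and Microsolvation Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for determining gas-phase peptide structures by combining
    fluorescence-lifetime FRET distance estimation, collision cross sections
    from the Monte-Carlo projection approximation with travelling-wave ion
    mobility calibration, simulated-annealing conformer generation in a
    reduced peptide representation, refinement of conformer ensembles against
    energy, CCS and donor-acceptor distance constraints, probe-grid
    microsolvation scoring of the refined structures, and differential ion
    mobility (DMS) ionogram analysis. Includes synthetic generators for decay
    histograms, calibrant tables and ionograms, and an end-to-end pipeline
    driver with a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
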