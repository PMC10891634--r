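Package: poresel
Title: Thermodynamics of Ion Selectivity in Nanopores with Desk-Scale Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytic Gibbs-energy model of ion selectivity in water-filled
    nanopores (hydration free energy versus solute size, critical radii,
    ion-membrane/ion-circle decomposition, energy-barrier maps), together with
    trajectory analyses of water structure (geometric hydrogen bonds, local
    bonding motifs, interfacial/bulk partition, radial distribution functions,
    first-shell coordination numbers) and a compact periodic Langevin simulator
    of rigid three-site water, monovalent ions and frozen graphene-like pore
    sheets, with an adaptive-biasing-force estimator of the potential of mean
    force along the ion-pore axis and constant-field crossing experiments.
    Synthetic-system generators make every analysis reproducible without
    external data.
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
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
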