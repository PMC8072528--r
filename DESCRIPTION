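Package: latfib
Title: Lattice Monte Carlo Simulation of Polypeptide Aggregation on Smooth
    and Rough Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coarse-grained cubic-lattice model of amyloid-like aggregation
    of short polypeptide chains near adsorbing surfaces.  Chains are
    self-avoiding walks of charged (+/-), hydrophobic (H) and polar (P)
    beads moved by Metropolis Monte Carlo dynamics (tail rotation, corner
    flip, crankshaft, rigid 90-degree rotations and unit translations).
    Smooth surfaces are planes of fixed hydrophilic (Ps) or hydrophobic
    (Hs) beads; rough surfaces add randomly placed single or double balls,
    parameterised by the coverage fraction and the root-mean-square
    roughness of the resulting height field.  The package estimates
    aggregation times as mean first-passage times to a configuration
    carrying 80 percent of the inter-chain contacts of a reference fibril,
    and provides scan drivers for surface-affinity and roughness sweeps
    together with exact desk-scale oracles (exhaustive conformation
    enumeration, Boltzmann sampling checks, closed-form roughness
    statistics) used to validate the machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
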