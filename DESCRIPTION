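Package: pocketeer
Title: Target-Restricted Deep-Pocket Detection and Pocket-Biased
    Conformational Sampling
Version: 0.1.0
Authors@R:
    person("Pocketeer", "Developers", email = "pocketeer@example.org",
           role = c("aut", "cre"))
Description: Detects "deep" surface pockets near a chosen target residue of
    a protein structure using a LIGSITE-style labelled grid (protein /
    surface / solvent classification, Surface-Solvent-Surface scan-line
    events, deep vs. surface pocket split, connected-component clustering),
    and couples the resulting deep-pocket volume to a simplified all-atom
    energy model as a linear biasing term for Metropolis Monte Carlo
    sampling over sidechain and backbone torsions.  Includes ensemble
    analytics (minimum interface RMSD to bound reference structures,
    pocket lining hydrophobic SASA fraction, cumulative volume curves,
    matched random surface-site selection), a synthetic-structure fixture
    generator with analytically known cavities, and a command-line
    interface.
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
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
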