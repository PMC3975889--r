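Package: ilerot
Title: Isoleucine Side-Chain Rotamer Geometry, Statistics and Steric
    Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for studying isoleucine side-chain torsion angles
    (chi1, chi2) in protein crystal structures: PDB and DSSP parsing with
    quality filtering, classification of observations into the nine
    120x120 degree rotamer sections, resolution-, secondary-structure-
    and refinement-software-stratified angle statistics with
    two-dimensional Gaussian optima, idealized alpha-helix and
    beta-hairpin builders, and an exhaustive chi1/chi2 conformational
    scan under a soft-sphere steric field with van der Waals-corrected
    contact maps.  A synthetic-structure generator with known rotamer
    distributions and a configurable resolution-dependent refinement bias
    supports end-to-end validation of every pipeline stage.
License: MIT + file LICENSE
Imports:
    bio3d,
    dplyr,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
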