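Package: forcekin
Title: Force-Dependent TCR/pMHC Bond Kinetics and Mechanical Proofreading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for single-bond force spectroscopy of T-cell
    receptor (TCR) interactions with peptide-MHC. Implements Bell's model of
    force-dependent off-rates and the fold-change calculus of antigen
    discrimination, laminar-flow-chamber hydrodynamics mapping bead velocity
    to bond force, survival analysis of bead-arrest lifetimes with
    non-specific-binding correction and quality filters, a structure-based
    one-bead-per-residue pulling simulator with Bell-Evans dynamic force
    spectroscopy fits, a force-modified kinetic proofreading model of T-cell
    antigen discrimination, and Langmuir/dissociation binding-affinity fits.
    Synthetic-data generators with known ground truth emulate every assay
    input so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
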