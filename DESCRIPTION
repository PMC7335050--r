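Package: groovemapper
Title: Mapping Alternative BH3-Binding Grooves from NMR Titrations,
    Conformer Ensembles and Binding Assays
Version: 0.1.0
Authors@R:
    person("Groovemapper", "Developers", email = "groovemapper@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse protein-peptide binding-groove usage on
    BCL2-family effectors such as BAK. Computes per-residue chemical shift
    perturbations (CSPs) from 1H,15N-HSQC titration peak lists, applies a
    mean-plus-one-standard-deviation threshold and classifies residues into
    dose-responsive shifts versus intensity loss to noise; maps classified
    residues onto structure-defined grooves (canonical alpha3/alpha4/alpha5
    versus noncanonical alpha4/alpha6/alpha7) with permutation-based
    enrichment; clusters conformer ensembles by best-fit Calpha RMSD with
    average linkage terminated at an epsilon cutoff and reports the
    population of the most populated conformer; fits steady-state SPR
    isotherms for dissociation constants with a saturation quality-control
    rule; and quantifies liposome dye-release assays. A synthetic-data
    module generates every input with known ground truth, and a config
    driven pipeline orchestrates the stages into a reproducible report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
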