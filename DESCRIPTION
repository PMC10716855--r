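Package: spidrosolv
Title: Secondary Structure, Hydrogen Bonding and Solvation Analysis of
    Spidroins in Water-Ethanol Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics studies of engineered
    spider-silk proteins (spidroins) in water-ethanol mixtures. Provides a
    lightweight topology/trajectory data model with PDB and GRO input and
    output, DSSP-style secondary-structure assignment with grouped fraction
    statistics and kernel-density summaries, geometric hydrogen-bond
    detection with intra- and intermolecular classification, per-residue
    solvation-shell density profiles, solvent cluster-size distributions
    under periodic boundaries, region-region radial distribution functions,
    equilibration diagnostics, and circular-dichroism post-processing
    (molar-ellipticity conversion and block-contribution subtraction).
    Synthetic-system generators (ideal and perturbed peptide conformations,
    solvated mixture boxes, pseudo-trajectories and CD fraction tables) make
    every stage testable without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
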