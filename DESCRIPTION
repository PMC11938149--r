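Package: nmrdock
Title: NMR-Guided Assessment of Protein-Protein Complex Models
Version: 0.1.0
Authors@R:
    person("nmrdock", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to validate candidate structures of transient
    protein-protein complexes against solution NMR titration data.
    Computes amide chemical shift perturbations (CSP) from apo/bound
    shift tables, detects peaks broadened beyond detectability, builds
    significance-thresholded perturbed-residue sets, extracts interface
    residues from complex models at an any-atom distance cutoff, scores
    and ranks models by interface coverage and error, computes
    Shrake-Rupley solvent accessible and buried surface areas, and
    analyses multi-frame trajectories (contact frequencies, hydrogen
    bonds, receptor-aligned ligand RMSD, hierarchical clustering with
    representative-frame selection).  Includes seed-deterministic
    synthetic-data generators with known ground truth, NOE restraint
    bookkeeping, mono-exponential relaxation fits and heteronuclear NOE
    ratios, plus a scriptable command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
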