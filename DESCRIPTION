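Package: epmm
Title: Pseudoatom Databank Electrostatics for Macromolecular Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs continuous aspherical molecular electron densities
    from transferable Hansen-Coppens pseudoatom multipole parameters and
    computes intermolecular electrostatic interaction energies with a hybrid
    exact-potential/multipole-moment (EPMM) scheme that captures charge
    penetration. Includes a databank-transfer step for protonated PDB
    structures (bond detection, neutron-distance hydrogen extension, atom
    typing, fragment charge scaling), a per-residue protein-RNA binding-site
    analysis pipeline, electrostatic potential maps on cubic grids with
    iso-density masking, and synthetic fixtures (analytic dimers and toy
    protein-RNA complexes) so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
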