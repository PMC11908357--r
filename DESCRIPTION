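Package: plcurate
Title: Curation of Non-Covalent Protein-Ligand Complex Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A curation workflow for protein-ligand crystal structures and
    their binding-affinity annotations. Deposited entries are split into
    ligand, protein and additive components; unusable complexes are rejected
    by four filters (covalent binders, rare elements, very small ligands,
    steric clashes); ligand chemistry is repaired by transferring bond
    orders, aromaticity and formal charges from a reference SMILES through
    element-labelled graph isomorphism, followed by rule-based protonation
    at physiological pH; protein chains are completed from header sequences
    using idealized residue templates; the recombined complex is relaxed
    under coordinate constraints so experimentally resolved atoms never
    move; and heterogeneous Kd/Ki/IC50/EC50 annotations are normalized to
    molar units with free energies for exact dissociation constants. A
    deterministic synthetic-complex generator with injectable defects makes
    every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
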