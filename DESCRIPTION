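Package: nciprofiler
Title: Geometric Profiling of Non-Covalent Interactions in Macromolecular Complexes
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects and reports eight classes of non-covalent interactions
    (hydrogen bonds, hydrophobic contacts, pi-stacking, pi-cation interactions,
    salt bridges, water bridges, metal complexes and halogen bonds) between
    ligands and macromolecular receptors from PDB-format structures. The
    receptor may be protein, DNA, RNA or a mixed complex: nucleic-acid
    residues can be treated either as receptor or as ligand entities. The
    pipeline parses and hydrogenates the structure, extracts ligands and
    binding sites, perceives chemical features (donors, acceptors, charged
    centres, aromatic rings, hydrophobic atoms, halogen donors, metals), then
    applies configurable geometric rules with deterministic refinement, and
    writes machine-readable XML and aligned-text reports. Includes a
    synthetic-fixture generator that writes PDB files with planted
    interactions and ground-truth manifests, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    tools,
    utils,
    xml2
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
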