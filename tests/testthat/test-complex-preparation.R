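rna5_pdb <- function() {
  # protein residue + 5-residue RNA chain U G G U G (consecutive numbering)
  groups <- list(mk_protein = nciprofiler:::mk_atoms(
    c("N", "CA", "C", "O"), c("N", "C", "C", "O"),
    rbind(c(0, 20, 0), c(1.46, 20, 0), c(2, 21.4, 0), c(1.25, 22.4, 0)),
    "GLY", "A", 10))
  bases <- c("U", "G", "G", "U", "G")
  for (i in seq_along(bases)) {
    b <- nciprofiler:::nucleobase_atoms(bases[i], "R", i)
    groups[[length(groups) + 1]] <- nciprofiler:::shift_atoms(b, c(7 * i, 0, 0))
  }
  atoms <- do.call(rbind, groups)
  atoms$serial <- seq_len(nrow(atoms)); atoms$model <- 1L
  s <- structure(list(
    atoms = atoms[, c("serial", "name", "altloc", "resname", "chain",
                      "resseq", "icode", "x", "y", "z", "occ", "element",
                      "hetero", "model")],
    conect = data.frame(from = integer(0), to = integer(0)),
    nmodels = 1L, selected_model = 1L, header_id = NA_character_),
    class = "nci_structure")
  f <- fixture_path("rna5")
  write_pdb(s, f)
  f
}

test_that("a lone hetero group becomes one small-molecule ligand entity", {
  fx <- standard_fixture("saltbridge_inside")
  s <- ensure_hydrogens(parse_pdb(fx$path))$structure
  ligs <- extract_ligands(s, analysis_mode())
  expect_equal(length(ligs), 1L)
  expect_equal(ligs[[1]]$kind, "small_molecule")
  expect_false(ligs[[1]]$composite)
})

test_that("a contiguous RNA chain is one nucleic_chain entity unless the nucleic-receptor mode is on", {
  f <- rna5_pdb()
  s <- ensure_hydrogens(parse_pdb(f))$structure

  ligs <- suppressMessages(extract_ligands(s, analysis_mode()))
  expect_equal(length(ligs), 1L)
  expect_equal(ligs[[1]]$kind, "nucleic_chain")
  expect_equal(length(ligs[[1]]$residue_keys), 5L)

  ligs2 <- suppressMessages(
    extract_ligands(s, analysis_mode(nucleic_acids_as_receptor = TRUE)))
  expect_equal(length(ligs2), 0L)
  # with no nucleic entity extracted, RNA residues are receptor candidates:
  # a site built around a probe ligand placed at a base would contain them
  atoms <- structure_atoms(s)
  expect_true(all(c("U", "G") %in% atoms$resname))
})

test_that("the mode flip conserves the nucleic residue set between ligand and receptor roles", {
  f <- rna5_pdb()
  s <- ensure_hydrogens(parse_pdb(f))$structure
  atoms <- structure_atoms(s)
  nuc_keys <- unique(nciprofiler:::res_key(atoms)[
    residue_kind(atoms$resname) %in% c("dna", "rna")])
  ligs <- suppressMessages(extract_ligands(s, analysis_mode()))
  lig_keys <- unlist(lapply(ligs, function(l) l$residue_keys))
  expect_setequal(lig_keys[grepl(":(U|G|A|C|DT|DA|DC|DG)$", lig_keys)],
                  nuc_keys)
})

test_that("binding-site membership follows the heavy-atom shell rule (brute-force check)", {
  lines <- c(
    "HETATM    1  C1  UNL L   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   1       7.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       8.000   0.000   0.000  1.00  0.00           C",
    "END")
  s <- parse_pdb(lines)
  lig <- suppressMessages(extract_ligands(s, analysis_mode()))[[1]]
  site <- build_binding_site(s, lig, cutoff = 7.5)
  expect_equal(length(site$receptor_keys), 1L)
  expect_equal(site$receptor_atoms$resseq, 1L)
  # no receptor at all: empty site still succeeds
  s0 <- parse_pdb(lines[c(1, 4)])
  lig0 <- suppressMessages(extract_ligands(s0, analysis_mode()))[[1]]
  site0 <- build_binding_site(s0, lig0, cutoff = 7.5)
  expect_equal(length(site0$receptor_keys), 0L)
})

test_that("enlarging the site cutoff never removes a receptor residue", {
  fx <- standard_fixture("metal_inside")
  s <- ensure_hydrogens(parse_pdb(fx$path))$structure
  lig <- extract_ligands(s, analysis_mode())[[1]]
  prev <- character(0)
  for (cutoff in c(2, 4, 6, 7.5, 10)) {
    keys <- build_binding_site(s, lig, cutoff)$receptor_keys
    expect_true(all(prev %in% keys))
    prev <- keys
  }
})

test_that("receptor and ligand atom sets are disjoint for every fixture site", {
  for (nm in c("hbond_inside", "pistacking_inside", "metal_inside",
               "halogen_nucleic")) {
    fx <- standard_fixture(nm)
    s <- ensure_hydrogens(parse_pdb(fx$path))$structure
    mode <- analysis_mode(nucleic_acids_as_receptor = fx$nucleic_mode)
    for (lig in suppressMessages(extract_ligands(s, mode))) {
      site <- build_binding_site(s, lig)
      expect_length(intersect(site$receptor_atoms$serial, lig$atoms$serial), 0)
    }
  }
})

test_that("intra-chain filtering removes own-chain receptor residues for polymer ligands only", {
  f <- rna5_pdb()
  s <- ensure_hydrogens(parse_pdb(f))$structure
  lig <- suppressMessages(extract_ligands(s, analysis_mode()))[[1]]
  # inject a same-chain protein-like residue next to the RNA for the test
  site <- build_binding_site(s, lig, cutoff = 30)
  expect_gt(length(site$receptor_keys), 0)
  same <- site
  same$receptor_atoms$chain <- lig$chain  # force own-chain receptor rows
  same$receptor_keys <- unique(nciprofiler:::res_key(same$receptor_atoms))
  filtered <- classify_receptor_scope(same, analysis_mode(intra_chain = FALSE))
  expect_equal(length(filtered$receptor_keys), 0L)
  kept <- classify_receptor_scope(same, analysis_mode(intra_chain = TRUE))
  expect_equal(kept$receptor_keys, same$receptor_keys)
  # small molecules are never filtered
  fx <- standard_fixture("hbond_inside")
  s2 <- ensure_hydrogens(parse_pdb(fx$path))$structure
  lig2 <- extract_ligands(s2, analysis_mode())[[1]]
  site2 <- build_binding_site(s2, lig2)
  expect_equal(
    classify_receptor_scope(site2,
                            analysis_mode(intra_chain = FALSE))$receptor_keys,
    site2$receptor_keys)
})

test_that("ubiquitous solvent residues are excluded from ligand candidacy unless restored", {
  lines <- c(
    "HETATM    1  C1  GOL L   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  O1  GOL L   1       1.430   0.000   0.000  1.00  0.00           O",
    "END")
  s <- parse_pdb(lines)
  expect_length(suppressMessages(extract_ligands(s, analysis_mode())), 0)
  restored <- extract_ligands(s, analysis_mode(ligand_exclusion_list = character(0)))
  expect_length(restored, 1)
})

test_that("covalently connected hetero residues merge into one composite entity", {
  lines <- c(
    "HETATM    1  C1  AAA L   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  C2  AAA L   1       1.500   0.000   0.000  1.00  0.00           C",
    "HETATM    3  C1  BBB L   2       2.900   0.000   0.000  1.00  0.00           C",
    "HETATM    4  C1  CCC L   3      12.000   0.000   0.000  1.00  0.00           C",
    "END")
  s <- parse_pdb(lines)
  ligs <- extract_ligands(s, analysis_mode())
  expect_equal(length(ligs), 2L)
  comp <- ligs[[which(vapply(ligs, function(l) l$composite, logical(1)))]]
  expect_equal(length(comp$residue_keys), 2L)
})

test_that("modified residues linked into a polymer stay with the receptor unless flagged", {
  lines <- c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  C1  XYZ A   2       1.500   0.000   0.000  1.00  0.00           C",
    "END")
  s <- parse_pdb(lines)
  expect_length(suppressMessages(extract_ligands(s, analysis_mode())), 0)
  ligs <- extract_ligands(s, analysis_mode(modified_residues_as_ligand = TRUE))
  expect_length(ligs, 1)
})

test_that("a lone metal ion is a ligand entity of kind ion", {
  fx <- standard_fixture("metal_inside")
  s <- ensure_hydrogens(parse_pdb(fx$path))$structure
  ligs <- extract_ligands(s, analysis_mode())
  expect_equal(ligs[[1]]$kind, "ion")
})
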