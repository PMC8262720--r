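# helper: hydrogenate + perceive a data frame of atoms built from fixture
# groups (serials assigned here)
perceive_built <- function(atoms_df, mode = analysis_mode()) {
  atoms_df$serial <- seq_len(nrow(atoms_df))
  atoms_df$model <- 1L
  s <- structure(list(
    atoms = atoms_df[, c("serial", "name", "altloc", "resname", "chain",
                         "resseq", "icode", "x", "y", "z", "occ", "element",
                         "hetero", "model")],
    conect = data.frame(from = integer(0), to = integer(0)),
    nmodels = 1L, selected_model = 1L, header_id = NA_character_),
    class = "nci_structure")
  s <- ensure_hydrogens(s)$structure
  perceive_features(structure_atoms(s), mode = mode)
}

asp_atoms <- function() {
  a <- 63 * pi / 180
  nciprofiler:::mk_atoms(
    c("N", "CA", "CB", "CG", "OD1", "OD2", "C", "O"),
    c("N", "C", "C", "C", "O", "O", "C", "O"),
    rbind(c(-2.9, 1.2, 0), c(-2.4, 0, 0), c(-1.52 + 0.6, 0, 1.2),
          c(0, 0, 0), 1.25 * c(cos(a), sin(a), 0),
          1.25 * c(cos(a), -sin(a), 0), c(-3.2, -1.1, 0), c(-3.0, -2.3, 0)),
    "ASP", "A", 25)
}

test_that("aspartate perceives one carboxylate negative centre over OD1/OD2", {
  f <- perceive_built(asp_atoms())
  expect_equal(nrow(f$neg_centers), 1L)
  expect_equal(f$neg_centers$kind, "carboxylate")
  nm <- sort(f$neg_centers$serials[[1]])
  expect_equal(length(nm), 2L)
  expect_equal(nrow(f$pos_centers), 0L)
  # unweighted centroid of the member coordinates
  expect_equal(c(f$neg_centers$cx, f$neg_centers$cy, f$neg_centers$cz),
               c(1.25 * cos(63 * pi / 180), 0, 0), tolerance = 1e-6)
})

test_that("phenylalanine perceives one planar 6-ring and no charged centres", {
  ring <- nciprofiler:::grp_phe_ring("A", 38)
  f <- perceive_built(ring)
  expect_equal(nrow(f$rings), 1L)
  expect_equal(length(f$rings$serials[[1]]), 6L)
  expect_lte(f$rings$rmsd, 0.25)
  expect_equal(nrow(f$pos_centers), 0L)
  expect_equal(nrow(f$neg_centers), 0L)
  # all six ring carbons are hydrophobic in the template
  expect_equal(nrow(f$hydrophobics), 6L)
})

test_that("arginine carries a guanidinium positive centre over NH1/NH2/NE/CZ", {
  f <- perceive_built(nciprofiler:::grp_arg_guanidinium("A", 42))
  expect_equal(nrow(f$pos_centers), 1L)
  expect_equal(f$pos_centers$kind, "guanidinium")
  expect_equal(length(f$pos_centers$serials[[1]]), 4L)
})

test_that("guanine (DG) contributes purine rings plus its base donor/acceptor pattern", {
  g <- nciprofiler:::nucleobase_atoms("DG", "B", 7)
  f <- perceive_built(g)
  expect_gte(nrow(f$rings), 2L)
  expect_true("fused" %in% f$rings$label)
  name_of <- function(serials) g$name[serials]
  accs <- g$name[f$acceptors$serial]
  expect_true(all(c("O6", "N7", "N3") %in% accs))
  dons <- g$name[f$donors$serial]
  expect_true(all(c("N1", "N2") %in% dons))
  expect_false(any(f$donors$no_h))   # hydrogenation supplied the base H's
})

test_that("a nucleotide phosphate is one negative centre over the free phosphate oxygens", {
  g <- nciprofiler:::nucleobase_atoms("DG", "B", 7)
  p <- nciprofiler:::mk_atoms(c("P", "OP1", "OP2"), c("P", "O", "O"),
                              rbind(c(8, 0, 0), c(8.9, 1.2, 0),
                                    c(8.9, -1.2, 0)),
                              "DG", "B", 7)
  f <- perceive_built(rbind(g, p))
  expect_equal(nrow(f$neg_centers), 1L)
  expect_equal(f$neg_centers$kind, "phosphate")
  expect_equal(length(f$neg_centers$serials[[1]]), 2L)
})

test_that("thymine's C7 methyl is hydrophobic while uracil has no methyl", {
  fu <- perceive_built(nciprofiler:::nucleobase_atoms("U", "R", 1))
  ft <- perceive_built(nciprofiler:::nucleobase_atoms("DT", "B", 1))
  u_names <- nciprofiler:::nucleobase_atoms("U", "R", 1)$name
  t_names <- nciprofiler:::nucleobase_atoms("DT", "B", 1)$name
  expect_true("C7" %in% t_names[ft$hydrophobics$serial])
  expect_false("C7" %in% u_names)
  # both share the pyrimidine C5 hydrophobic carbon
  expect_true("C5" %in% u_names[fu$hydrophobics$serial])
})

test_that("generic perception: benzene is one aromatic ring of hydrophobic carbons with no donors", {
  f <- perceive_built(nciprofiler:::grp_benzene("UNL", "L", 1))
  expect_equal(nrow(f$rings), 1L)
  expect_equal(nrow(f$hydrophobics), 6L)
  expect_equal(nrow(f$donors), 0L)
  expect_equal(nrow(f$acceptors), 0L)
})

test_that("generic perception: a carbon-bound chlorine is a halogen donor; fluorine is excluded by default", {
  clb <- rbind(nciprofiler:::grp_benzene("UNL", "L", 1),
               nciprofiler:::mk_atoms("CL1", "Cl", c(1.39 + 1.74, 0, 0),
                                      "UNL", "L", 1, hetero = TRUE))
  f <- perceive_built(clb)
  expect_equal(nrow(f$halogen_donors), 1L)
  flb <- clb
  flb$element[flb$name == "CL1"] <- "F"
  expect_equal(nrow(perceive_built(flb)$halogen_donors), 0L)
  expect_equal(nrow(perceive_built(
    flb, analysis_mode(halogen_include_fluorine = TRUE))$halogen_donors), 1L)
})

test_that("feature perception is invariant to atom input order", {
  g <- nciprofiler:::nucleobase_atoms("G", "R", 3)
  f1 <- perceive_built(g)
  set.seed(11)
  g2 <- g[sample(nrow(g)), ]
  f2 <- perceive_built(g2)
  # compare by atom name, not serial (serials follow input order)
  sig <- function(f, df, what) sort(df$name[f[[what]]$serial])
  for (w in c("donors", "acceptors", "hydrophobics"))
    expect_equal(sig(f2, g2, w), sig(f1, g, w))
  expect_equal(nrow(f2$rings), nrow(f1$rings))
  expect_equal(sort(f2$rings$label), sort(f1$rings$label))
})

test_that("a quaternary nitrogen is never an acceptor and counts as a positive centre", {
  n <- nciprofiler:::mk_atoms(
    c("N1", "C1", "C2", "C3", "C4"), c("N", "C", "C", "C", "C"),
    rbind(c(0, 0, 0), c(1.5, 0, 0), c(-1.5, 0, 0), c(0, 1.5, 0),
          c(0, -1.5, 0)),
    "UNL", "L", 1, hetero = TRUE)
  f <- perceive_built(n)
  expect_false(1 %in% f$acceptors$serial)
  expect_equal(nrow(f$pos_centers), 1L)
  expect_equal(f$pos_centers$kind, "amine")
})

test_that("ring plane angles are insensitive to the normal's sign", {
  n <- c(0.3, -0.5, 0.81)
  expect_equal(nciprofiler:::plane_angle(n, -n), 0, tolerance = 1e-9)
  expect_equal(nciprofiler:::plane_angle(c(0, 0, 1), c(1, 0, 0)), 90)
})

test_that("histidine becomes cationic only when both ring nitrogens are protonated", {
  his <- nciprofiler:::mk_atoms(
    c("CG", "ND1", "CD2", "CE1", "NE2"), c("C", "N", "C", "C", "N"),
    rbind(c(1.14, 0, 0), c(0.35, 1.08, 0), c(0.35, -1.08, 0),
          c(-0.92, 0.67, 0), c(-0.92, -0.67, 0)),
    "HIS", "A", 5)
  f_default <- perceive_built(his)   # hydrogenation protonates NE2 only
  expect_equal(nrow(f_default$pos_centers), 0L)
  expect_true(any(f_default$acceptors$serial == 2))  # ND1 acceptor

  # explicit hydrogens on both nitrogens: imidazolium
  h2 <- nciprofiler:::mk_atoms(
    c("HD1", "HE2"), c("H", "H"),
    rbind(c(0.55, 2.07, 0), c(-1.5, -1.47, 0)),
    "HIS", "A", 5)
  f_charged <- perceive_built(rbind(his, h2))
  expect_equal(nrow(f_charged$pos_centers), 1L)
  expect_equal(f_charged$pos_centers$kind, "imidazolium")
  expect_false(2 %in% f_charged$acceptors$serial)
})

test_that("the shipped template table and the perception code agree on hand-enumerated rows", {
  tmpl <- nciprofiler:::load_templates()
  # spot checks against textbook assignments
  row_of <- function(res, feat) sort(tmpl$atom[tmpl$residue == res &
                                                 tmpl$feature == feat])
  expect_equal(row_of("ASP", "neg"), c("OD1", "OD2"))
  expect_equal(row_of("ARG", "pos"), c("CZ", "NE", "NH1", "NH2"))
  expect_equal(row_of("PHE", "ring1"),
               sort(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")))
  expect_equal(row_of("G", "donor"), sort(c("N1", "N2", "O2'")))
  expect_equal(row_of("DG", "donor"), c("N1", "N2"))
  expect_equal(row_of("DT", "hydrophobic"), sort(c("C2'", "C5", "C7")))
  expect_equal(row_of("U", "hydrophobic"), "C5")
})
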