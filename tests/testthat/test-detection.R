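cfg <- default_config()

test_that("hydrophobic contacts honour the inclusive distance cutoff and the reduction rule", {
  cases <- list(list(d = 3.8, n = 1), list(d = 4.0, n = 1), list(d = 4.2, n = 0))
  for (cs in cases) {
    atoms <- mk_atom_table(rbind(c(0, 0, 0), c(cs$d, 0, 0)))
    lf <- features_from(hydrophobics = ff_hydrophobic(1L))
    rf <- features_from(hydrophobics = ff_hydrophobic(2L, "ALA", "A", 1L))
    out <- detect_hydrophobic(lf, rf, atoms, cfg)
    expect_equal(nrow(out), cs$n)
    if (cs$n) expect_equal(out$dist, cs$d, tolerance = 1e-9)
  }
  # 3 ligand carbons against 1 receptor carbon collapse to the closest pair
  atoms <- mk_atom_table(rbind(c(3.5, 0, 0), c(0, 3.7, 0), c(0, 0, 3.9),
                               c(0, 0, 0)))
  lf <- features_from(hydrophobics = ff_hydrophobic(1:3))
  rf <- features_from(hydrophobics = ff_hydrophobic(4L, "ALA", "A", 1L))
  out <- detect_hydrophobic(lf, rf, atoms, cfg)
  expect_equal(nrow(out), 1L)
  expect_equal(out$dist, 3.5)
  expect_equal(out$lig_serials, "1")
})

hb_case <- function(d, ang) {
  atoms <- rbind(mk_atom_table(matrix(c(0, 0, 0), 1), 1L, "N"),
                 mk_atom_table(matrix(c(0, 0, 1.01), 1), 2L, "H"),
                 mk_atom_table(matrix(
                   d * c(sin(ang * pi / 180 - pi), 0,
                         cos(ang * pi / 180 - pi)) * -1, 1), 3L, "O"))
  # place the acceptor so that the D-H...A angle is approximately `ang`
  # by the law of sines construction used in the fixture generator
  A <- nciprofiler:::solve_hbond_acceptor(c(0, 0, 0), c(0, 0, 1.01), d, ang)
  atoms[3, c("x", "y", "z")] <- A
  lf <- features_from(donors = ff_donors(1L, list(2L)))
  rf <- features_from(acceptors = ff_acceptors(3L, resname = "ALA",
                                               chain = "A"))
  detect_hbonds(lf, rf, atoms, cfg)
}

test_that("hydrogen bonds require both the distance and the donor-angle rule", {
  hit <- hb_case(2.9, 165)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$dist, 2.9, tolerance = 1e-6)
  expect_equal(hit$angle, 165, tolerance = 1e-6)
  expect_equal(hit$donor_side, "ligand")
  expect_false(hit$unverified)
  expect_equal(nrow(hb_case(2.9, 80)), 0L)
  expect_equal(nrow(hb_case(4.3, 165)), 0L)
  # just inside the inclusive bounds (exact-boundary behaviour is covered
  # at PDB precision by the fixture suite)
  expect_equal(nrow(hb_case(4.099, 165)), 1L)
  expect_equal(nrow(hb_case(2.9, 100.01)), 1L)
  expect_equal(nrow(hb_case(2.9, 99.9)), 0L)
})

test_that("a donor without a placeable hydrogen degrades to a flagged distance-only candidate", {
  atoms <- rbind(mk_atom_table(matrix(c(0, 0, 0), 1), 1L, "N"),
                 mk_atom_table(matrix(c(2.9, 0, 0), 1), 3L, "O"))
  lf <- features_from(donors = ff_donors(1L, list(integer(0)), no_h = TRUE))
  rf <- features_from(acceptors = ff_acceptors(3L, resname = "ALA",
                                               chain = "A"))
  out <- detect_hbonds(lf, rf, atoms, cfg)
  expect_equal(nrow(out), 1L)
  expect_true(out$unverified)
  expect_true(is.na(out$angle))
})

test_that("nucleic ligand donors hydrogen-bond to protein acceptors with the nucleic flag on the ligand side", {
  fx <- standard_fixture("hbond_nucleic_ligand")
  p <- profile_complex(fx$path)
  ints <- profile_interactions(p)
  expect_equal(nrow(ints), 1L)
  expect_equal(ints$type, "hbond")
  expect_false(ints$receptor_is_nucleic)
  expect_equal(residue_kind(ints$lig_resname), "rna")
})

wb_case <- function(d1, d2, om) {
  wo <- c(0, 0, 0)
  atoms <- rbind(
    mk_atom_table(matrix(c(d1, 0, 0), 1), 1L, "O"),
    mk_atom_table(matrix(d2 * c(cos(om * pi / 180), sin(om * pi / 180), 0), 1),
                  100L, "O"),
    mk_atom_table(matrix(wo, 1), 200L, "O"))
  lf <- features_from(acceptors = ff_acceptors(1L))
  rf <- features_from(donors = ff_donors(100L, list(integer(0)),
                                         resname = "SER", chain = "A"))
  waters <- data.frame(serial = 200L, resname = "HOH", chain = "W",
                       resseq = 1L, icode = "", stringsAsFactors = FALSE)
  detect_water_bridges(lf, rf, waters, atoms, cfg)
}

test_that("water bridges require both legs in range, the omega window and donor/acceptor asymmetry", {
  hit <- wb_case(2.8, 2.8, 110)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$angle, 110, tolerance = 1e-6)
  expect_equal(hit$water_serial, 200L)
  expect_equal(nrow(wb_case(4.5, 2.8, 110)), 0L)
  expect_equal(nrow(wb_case(2.8, 2.8, 60)), 0L)
  expect_equal(nrow(wb_case(2.3, 2.8, 110)), 0L)   # below the minimum leg
  # acceptor-acceptor legs never bridge
  atoms <- rbind(mk_atom_table(matrix(c(2.8, 0, 0), 1), 1L, "O"),
                 mk_atom_table(matrix(c(-2.8, 0, 0), 1), 100L, "O"),
                 mk_atom_table(matrix(c(0, 0, 0), 1), 200L, "O"))
  lf <- features_from(acceptors = ff_acceptors(1L))
  rf <- features_from(acceptors = ff_acceptors(100L, resname = "SER",
                                               chain = "A"))
  waters <- data.frame(serial = 200L, resname = "HOH", chain = "W",
                       resseq = 1L, icode = "", stringsAsFactors = FALSE)
  expect_equal(nrow(detect_water_bridges(lf, rf, waters, atoms, cfg)), 0L)
})

test_that("salt bridges pair opposite charges within the centroid cutoff", {
  sb <- function(d, swap = FALSE) {
    lf <- features_from(pos_centers = ff_centers(c(0, 0, 0), "guanidinium",
                                                 list(1:4)))
    rf <- features_from(neg_centers = ff_centers(c(d, 0, 0), "carboxylate",
                                                 list(100:101),
                                                 resname = "ASP", chain = "A"))
    if (swap) {
      tmp <- lf$pos_centers
      lf <- features_from(neg_centers = ff_centers(c(0, 0, 0), "phosphate",
                                                   list(1:3)))
      rf <- features_from(pos_centers = ff_centers(c(d, 0, 0), "amine",
                                                   list(100L),
                                                   resname = "LYS",
                                                   chain = "A"))
    }
    detect_salt_bridges(lf, rf, mk_atom_table(matrix(0, 1, 3)), cfg)
  }
  expect_equal(nrow(sb(4.0)), 1L)
  expect_equal(nrow(sb(5.5)), 1L)     # inclusive boundary
  expect_equal(nrow(sb(6.0)), 0L)
  # ligand-side negative (phosphate vs ammonium), mirroring a nucleotide tail
  hit <- sb(4.5, swap = TRUE)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$geom_label, "positive_receptor")
  # like charges never pair
  lf <- features_from(pos_centers = ff_centers(c(0, 0, 0), "amine", list(1L)))
  rf <- features_from(pos_centers = ff_centers(c(3, 0, 0), "amine",
                                               list(100L), resname = "LYS",
                                               chain = "A"))
  expect_equal(nrow(detect_salt_bridges(lf, rf,
                                        mk_atom_table(matrix(0, 1, 3)), cfg)),
               0L)
})

ps_case <- function(d, ang, off, tshape = FALSE) {
  n2 <- if (tshape) c(1, 0, 0) else
    c(sin(ang * pi / 180), 0, cos(ang * pi / 180))
  lf <- features_from(rings = ff_rings(c(0, 0, 0), c(0, 0, 1), list(1:6)))
  rf <- features_from(rings = ff_rings(c(off, 0, sqrt(d^2 - off^2)), n2,
                                       list(101:106), resname = "PHE",
                                       chain = "A"))
  detect_pistacking(lf, rf, mk_atom_table(matrix(0, 1, 3)), cfg)
}

test_that("pi-stacking distinguishes parallel and T-shaped windows and rejects oblique pairs", {
  par <- ps_case(3.8, 0, 0.5)
  expect_equal(nrow(par), 1L)
  expect_equal(par$geom_label, "P")
  expect_equal(par$offset, 0.5, tolerance = 1e-6)
  tsh <- ps_case(5.0, NA, 0, tshape = TRUE)
  expect_equal(tsh$geom_label, "T")
  expect_equal(nrow(ps_case(4.5, 45, 0.5)), 0L)
  expect_equal(nrow(ps_case(5.6, 0, 0)), 0L)
  expect_equal(nrow(ps_case(3.8, 0, 2.1)), 0L)
})

test_that("pi-cation requires proximity, plus a face-on approach for guanidinium", {
  pc <- function(d, in_plane = FALSE, kind = "guanidinium") {
    ctr <- if (in_plane) c(d, 0, 0) else c(0, 0, d)
    lf <- features_from(rings = ff_rings(c(0, 0, 0), c(0, 0, 1), list(1:6)))
    rf <- features_from(pos_centers = ff_centers(ctr, kind, list(100:103),
                                                 resname = "ARG", chain = "A"))
    detect_pication(lf, rf, mk_atom_table(matrix(0, 1, 3)), cfg)
  }
  expect_equal(nrow(pc(4.0)), 1L)
  expect_equal(nrow(pc(6.0)), 1L)                 # inclusive boundary
  expect_equal(nrow(pc(6.5)), 0L)
  expect_equal(nrow(pc(4.0, in_plane = TRUE)), 0L)  # sigma-face rule
  expect_equal(nrow(pc(4.0, in_plane = TRUE, kind = "amine")), 1L)
})

hal_case <- function(d, da, aa) {
  phi <- (180 - da) * pi / 180
  A <- d * c(cos(phi), sin(phi), 0)
  ydir <- as.numeric(nciprofiler:::rotate_about(
    matrix(nciprofiler:::unit(-A), 1), c(0, 0, 1), aa))
  atoms <- rbind(mk_atom_table(matrix(c(-1.77, 0, 0), 1), 1L, "C"),
                 mk_atom_table(matrix(c(0, 0, 0), 1), 2L, "Cl"),
                 mk_atom_table(matrix(A, 1), 100L, "O"),
                 mk_atom_table(matrix(A + 1.23 * ydir, 1), 101L, "C"))
  lf <- features_from(halogen_donors = cbind(
    data.frame(x_serial = 2L, c_serial = 1L), meta_df(1)))
  rf <- features_from(acceptors = ff_acceptors(100L, 101L, resname = "ALA",
                                               chain = "A"))
  detect_halogen_bonds(lf, rf, atoms, cfg)
}

test_that("halogen bonds require the sigma-hole donor angle and the acceptor angle", {
  hit <- hal_case(3.3, 170, 120)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$angle, 170, tolerance = 1e-6)
  expect_equal(hit$angle2, 120, tolerance = 1e-6)
  expect_equal(nrow(hal_case(3.3, 120, 120)), 0L)   # sigma hole misaligned
  expect_equal(nrow(hal_case(4.2, 170, 120)), 0L)
  expect_equal(nrow(hal_case(3.99, 165, 149.9)), 1L)  # near the tolerance edges
  expect_equal(nrow(hal_case(3.3, 170, 155)), 0L)
})

test_that("metal coordination groups the sphere per metal and labels idealised geometry", {
  oct <- rbind(c(2.1, 0, 0), c(-2.1, 0, 0), c(0, 2.1, 0), c(0, -2.1, 0),
               c(0, 0, 2.1), c(0, 0, -2.1))
  atoms <- rbind(mk_atom_table(matrix(c(0, 0, 0), 1), 1L, "Mg"),
                 mk_atom_table(oct, 100L, "O"))
  lf <- features_from(metals = cbind(data.frame(serial = 1L, element = "Mg"),
                                     meta_df(1, "MG")))
  rf <- features_from(acceptors = ff_acceptors(100:105, resname = "ASP",
                                               chain = "A"))
  out <- detect_metal_complexes(lf, rf, NULL, atoms, cfg)
  expect_equal(nrow(out), 6L)
  expect_true(all(out$geom_label == "octahedral"))
  expect_true(all(out$coord_num == 6L))

  # tetrahedral arrangement
  tet <- 2.0 * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
    sqrt(3)
  atoms2 <- rbind(mk_atom_table(matrix(c(0, 0, 0), 1), 1L, "Zn"),
                  mk_atom_table(tet, 100L, "O"))
  rf2 <- features_from(acceptors = ff_acceptors(100:103, resname = "CYS",
                                                chain = "A"))
  out2 <- detect_metal_complexes(lf, rf2, NULL, atoms2, cfg)
  expect_true(all(out2$geom_label == "tetrahedral"))

  # single partner: degenerate sphere
  atoms3 <- rbind(mk_atom_table(matrix(c(0, 0, 0), 1), 1L, "Mg"),
                  mk_atom_table(matrix(c(3.0, 0, 0), 1), 100L, "O"))
  out3 <- detect_metal_complexes(lf, features_from(
    acceptors = ff_acceptors(100L, resname = "ASP", chain = "A")),
    NULL, atoms3, cfg)
  expect_equal(nrow(out3), 1L)
  expect_equal(out3$geom_label, "other/underdetermined")
  # beyond the cutoff: nothing
  atoms4 <- atoms3; atoms4$x[2] <- 3.4
  expect_equal(nrow(detect_metal_complexes(lf, features_from(
    acceptors = ff_acceptors(100L, resname = "ASP", chain = "A")),
    NULL, atoms4, cfg)), 0L)
})

test_that("refinement: a salt bridge subsumes hydrogen bonds between its member atoms", {
  # carboxylate-guanidinium at combined H-bond + salt-bridge geometry
  atoms <- rbind(mk_atom_table(rbind(c(0, 0.5, 0), c(0, -0.5, 0)), 1L, "O"),
                 mk_atom_table(matrix(c(2.9, 0.5, 0), 1), 100L, "N"),
                 mk_atom_table(matrix(c(1.9, 0.5, 0), 1), 104L, "H"))
  lf <- features_from(
    neg_centers = ff_centers(c(0, 0, 0), "carboxylate", list(1:2)),
    acceptors = ff_acceptors(1:2))
  rf <- features_from(
    pos_centers = ff_centers(c(2.9, 0.5, 0), "guanidinium", list(100L),
                             resname = "ARG", chain = "A"),
    donors = ff_donors(100L, list(104L), resname = "ARG", chain = "A"))
  raw <- rbind(detect_hbonds(lf, rf, atoms, cfg),
               detect_salt_bridges(lf, rf, atoms, cfg))
  expect_true(any(raw$type == "hbond"))
  refined <- refine_interactions(raw, lf, rf)
  expect_equal(sum(refined$type == "saltbridge"), 1L)
  expect_equal(sum(refined$type == "hbond"), 0L)
})

test_that("refinement: a direct hydrogen bond suppresses the water bridge on the same atom pair", {
  fx <- standard_fixture("waterbridge_inside")
  # shrink the arrangement: bring the two polar atoms within direct H-bond
  # range while keeping the water -> both records would fire raw
  atoms <- rbind(mk_atom_table(matrix(c(3.4, 0, 0), 1), 1L, "O"),
                 mk_atom_table(matrix(c(0, 0, 0), 1), 100L, "O"),
                 mk_atom_table(matrix(c(0.96, 0, 0), 1), 101L, "H"),
                 mk_atom_table(matrix(c(1.7, 2.2, 0), 1), 200L, "O"))
  lf <- features_from(acceptors = ff_acceptors(1L))
  rf <- features_from(donors = ff_donors(100L, list(101L), resname = "SER",
                                         chain = "A"))
  waters <- data.frame(serial = 200L, resname = "HOH", chain = "W",
                       resseq = 1L, icode = "", stringsAsFactors = FALSE)
  raw <- rbind(detect_hbonds(lf, rf, atoms, cfg),
               detect_water_bridges(lf, rf, waters, atoms, cfg))
  expect_setequal(unique(raw$type), c("hbond", "waterbridge"))
  refined <- refine_interactions(raw, lf, rf)
  expect_equal(sum(refined$type == "hbond"), 1L)
  expect_equal(sum(refined$type == "waterbridge"), 0L)
})

test_that("refinement: purine multi-ring stacks reduce to the best-offset record; unrelated rows survive", {
  lf <- features_from(rings = ff_rings(
    rbind(c(0, 0, 0), c(1.2, 0, 0), c(0.6, 0, 0)),
    rbind(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1)),
    list(1:6, 7:11, 1:11), groups = c("pur", "pur", "pur")))
  rf <- features_from(rings = ff_rings(c(0.2, 0, 3.8), c(0, 0, 1),
                                       list(101:106), resname = "PHE",
                                       chain = "A"))
  raw <- detect_pistacking(lf, rf, mk_atom_table(matrix(0, 1, 3)), cfg)
  expect_equal(nrow(raw), 3L)
  refined <- refine_interactions(raw, lf, rf)
  expect_equal(nrow(refined), 1L)
  expect_equal(refined$offset, min(raw$offset), tolerance = 1e-9)

  # an independent hydrogen bond elsewhere is untouched by ring refinement
  atoms <- rbind(mk_atom_table(matrix(c(50, 0, 0), 1), 300L, "N"),
                 mk_atom_table(matrix(c(50, 0, 1.01), 1), 301L, "H"),
                 mk_atom_table(matrix(c(50, 0, 2.9), 1), 302L, "O"))
  lf2 <- features_from(donors = ff_donors(300L, list(301L)))
  rf2 <- features_from(acceptors = ff_acceptors(302L, resname = "ALA",
                                                chain = "A"))
  hb <- detect_hbonds(lf2, rf2, atoms, cfg)
  refined2 <- refine_interactions(rbind(raw, hb), lf, rf)
  expect_equal(sum(refined2$type == "hbond"), 1L)
})

test_that("refinement: one hydrogen bond per donor atom, best donor angle retained", {
  # one donor, two acceptors, both within range; angles 165 vs 120
  A1 <- nciprofiler:::solve_hbond_acceptor(c(0, 0, 0), c(0, 0, 1.01), 2.9, 165)
  A2 <- nciprofiler:::solve_hbond_acceptor(c(0, 0, 0), c(0, 0, 1.01), 3.2, 120)
  atoms <- rbind(mk_atom_table(matrix(c(0, 0, 0), 1), 1L, "N"),
                 mk_atom_table(matrix(c(0, 0, 1.01), 1), 2L, "H"),
                 mk_atom_table(matrix(A1, 1), 100L, "O"),
                 mk_atom_table(matrix(A2, 1), 101L, "O"))
  lf <- features_from(donors = ff_donors(1L, list(2L)))
  rf <- features_from(acceptors = ff_acceptors(100:101, resname = "ALA",
                                               chain = "A"))
  raw <- detect_hbonds(lf, rf, atoms, cfg)
  expect_equal(nrow(raw), 2L)
  refined <- refine_interactions(raw, lf, rf)
  expect_equal(nrow(refined), 1L)
  expect_equal(refined$acc_serial, 100L)
})

test_that("raising any distance threshold never removes an interaction (monotonicity)", {
  for (nm in c("hydrophobic_inside", "hbond_inside", "saltbridge_inside",
               "pistacking_inside", "pication_inside", "halogen_inside",
               "metal_inside")) {
    base <- profile_fixture(nm)
    n0 <- nrow(profile_interactions(base))
    wider <- update_config(default_config(),
                           hydroph_dist_max = 5, hbond_dist_max = 5,
                           saltbridge_dist_max = 7, pistack_dist_max = 7,
                           pication_dist_max = 8, halogen_dist_max = 5,
                           metal_dist_max = 3.5)
    n1 <- nrow(profile_interactions(profile_fixture(nm, config = wider)))
    expect_gte(n1, n0)
  }
  # lowering the donor-angle minimum never removes a hydrogen bond
  strict <- profile_interactions(profile_fixture("hbond_inside"))
  lax <- profile_interactions(profile_fixture(
    "hbond_inside", config = update_config(hbond_don_angle_min = 60)))
  expect_true(all(paste(strict$lig_serials, strict$rec_serials) %in%
                    paste(lax$lig_serials, lax$rec_serials)))
})

test_that("swapping ligand and receptor feature sets yields the same geometric pairs with roles exchanged", {
  fx <- standard_fixture("hbond_receptor_donor")
  s <- ensure_hydrogens(parse_pdb(fx$path))$structure
  atoms <- structure_atoms(s)
  lig <- extract_ligands(s, analysis_mode())[[1]]
  site <- build_binding_site(s, lig)
  lf <- perceive_features(lig$atoms)
  rf <- perceive_features(site$receptor_atoms)
  fwd <- detect_hbonds(lf, rf, atoms, cfg)
  rev <- detect_hbonds(rf, lf, atoms, cfg)
  expect_equal(nrow(fwd), nrow(rev))
  expect_setequal(paste(fwd$don_serial, fwd$acc_serial),
                  paste(rev$don_serial, rev$acc_serial))
  # donor/acceptor roles stay attached to the atoms, not the sides
  expect_equal(sort(fwd$donor_side), sort(ifelse(rev$donor_side == "ligand",
                                                 "receptor", "ligand")))
})

test_that("every reported geometry value satisfies the active thresholds (post-hoc audit)", {
  for (nm in names(standard_fixture_specs())) {
    ints <- profile_interactions(profile_fixture(nm))
    for (i in seq_len(nrow(ints))) {
      r <- ints[i, ]
      switch(r$type,
        hydrophobic = expect_lte(r$dist, cfg$hydroph_dist_max),
        hbond = {
          expect_lte(r$dist, cfg$hbond_dist_max)
          if (!is.na(r$angle)) expect_gte(r$angle, cfg$hbond_don_angle_min)
        },
        waterbridge = {
          expect_true(r$dist >= cfg$water_bridge_mindist &&
                        r$dist <= cfg$water_bridge_maxdist)
          expect_true(r$angle >= cfg$water_bridge_omega_min &&
                        r$angle <= cfg$water_bridge_omega_max)
        },
        saltbridge = expect_lte(r$dist, cfg$saltbridge_dist_max),
        pistacking = {
          expect_lte(r$dist, cfg$pistack_dist_max)
          expect_lte(r$offset, cfg$pistack_offset_max)
          expect_true(r$angle <= cfg$pistack_ang_dev ||
                        r$angle >= 90 - cfg$pistack_ang_dev)
        },
        pication = expect_lte(r$dist, cfg$pication_dist_max),
        halogen = {
          expect_lte(r$dist, cfg$halogen_dist_max)
          expect_lte(abs(r$angle - cfg$halogen_don_angle),
                     cfg$halogen_don_angle_dev)
        },
        metal = expect_lte(r$dist, cfg$metal_dist_max))
    }
  }
})
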