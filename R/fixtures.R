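#' @title Synthetic fixture generation
#'
#' @description
#' Writes syntactically valid PDB files containing minimal chemical groups
#' (formamide donors, benzene rings, nucleobases, phosphates, waters, metals
#' with coordination spheres, ...) arranged at requested geometry, plus decoy
#' atoms, together with a ground-truth manifest of the planted interactions.
#' Fixtures are the package's validation substrate: every interaction class
#' has inside-threshold, at-threshold (boundary) and outside-threshold
#' arrangements.
#'
#' Coordinates are rounded to PDB precision (3 decimals) before the manifest
#' geometry is measured, so re-measuring the written file reproduces the
#' manifest exactly.
#'
#' @name fixtures
NULL

mk_atoms <- function(names, elements, xyz, resname, chain, resseq,
                     hetero = FALSE, tags = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  data.frame(name = names, element = elements,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             resname = resname, chain = chain, resseq = as.integer(resseq),
             icode = "", altloc = "", occ = 1, hetero = hetero,
             tag = if (is.null(tags)) names else tags,
             stringsAsFactors = FALSE)
}

shift_atoms <- function(a, v) {
  a$x <- a$x + v[1]; a$y <- a$y + v[2]; a$z <- a$z + v[3]
  a
}

rotate_atoms <- function(a, axis, angle_deg, center = c(0, 0, 0)) {
  pts <- sweep(as.matrix(a[, c("x", "y", "z")]), 2, center)
  pts <- rotate_about(pts, axis, angle_deg)
  pts <- sweep(pts, 2, center, "+")
  a$x <- pts[, 1]; a$y <- pts[, 2]; a$z <- pts[, 3]
  a
}

hexagon <- function(r = 1.39) {
  th <- (seq_len(6) - 1) * 60 * pi / 180
  cbind(r * cos(th), r * sin(th), 0)
}

grp_benzene <- function(resname = "UNL", chain = "L", resseq = 1,
                        names = paste0("C", 1:6)) {
  mk_atoms(names, rep("C", 6), hexagon(), resname, chain, resseq,
           hetero = TRUE)
}

grp_phe_ring <- function(chain = "A", resseq = 1) {
  mk_atoms(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"), rep("C", 6),
           hexagon(), "PHE", chain, resseq)
}

grp_formamide_donor <- function(chain = "L", resseq = 1) {
  # N at origin, H along +z; C/O trail off at sp2 geometry
  dirC <- c(sin(120 * pi / 180), 0, cos(120 * pi / 180))
  C1 <- 1.33 * dirC
  O1 <- C1 + 1.23 * dirC
  mk_atoms(c("N1", "H1", "C1", "O1"), c("N", "H", "C", "O"),
           rbind(c(0, 0, 0), c(0, 0, 1.01), C1, O1),
           "UNL", chain, resseq, hetero = TRUE)
}

grp_water <- function(chain = "W", resseq = 1, with_h = FALSE) {
  if (with_h) {
    a <- 104.52 * pi / 180
    mk_atoms(c("O", "H1", "H2"), c("O", "H", "H"),
             rbind(c(0, 0, 0), c(0.9572, 0, 0),
                   0.9572 * c(cos(a), sin(a), 0)),
             "HOH", chain, resseq, hetero = TRUE)
  } else {
    mk_atoms("O", "O", c(0, 0, 0), "HOH", chain, resseq, hetero = TRUE)
  }
}

grp_ammonium <- function(chain = "L", resseq = 1) {
  # tetrahedral NH4+
  d <- 1.01 / sqrt(3)
  mk_atoms(c("N1", "H1", "H2", "H3", "H4"), c("N", rep("H", 4)),
           rbind(c(0, 0, 0), d * c(1, 1, 1), d * c(1, -1, -1),
                 d * c(-1, 1, -1), d * c(-1, -1, 1)),
           "UNL", chain, resseq, hetero = TRUE)
}

grp_acetate <- function(chain = "L", resseq = 1) {
  # carboxylate C at origin, O's fanning +x, methyl at -x
  a <- 63 * pi / 180
  mk_atoms(c("C1", "C2", "O1", "O2"), c("C", "C", "O", "O"),
           rbind(c(0, 0, 0), c(-1.52, 0, 0),
                 1.25 * c(cos(a), sin(a), 0), 1.25 * c(cos(a), -sin(a), 0)),
           "UNL", chain, resseq, hetero = TRUE)
}

grp_arg_guanidinium <- function(chain = "A", resseq = 1, with_h = TRUE) {
  # planar CZ + NE/NH1/NH2 in z = 0; in-plane hydrogens
  th <- c(90, 210, 330) * pi / 180
  Ns <- cbind(1.33 * cos(th), 1.33 * sin(th), 0)
  nm <- c("CZ", "NE", "NH1", "NH2")
  el <- c("C", "N", "N", "N")
  xyz <- rbind(c(0, 0, 0), Ns)
  if (with_h) {
    for (i in 1:3) {
      base <- Ns[i, ]
      out <- unit(base)
      side <- pracma_cross(c(0, 0, 1), out)
      h1 <- base + 1.01 * unit(out + 0.8 * side)
      h2 <- base + 1.01 * unit(out - 0.8 * side)
      nm <- c(nm, paste0("HH", i, "1"), paste0("HH", i, "2"))
      el <- c(el, "H", "H")
      xyz <- rbind(xyz, h1, h2)
    }
  }
  mk_atoms(nm, el, xyz, "ARG", chain, resseq)
}

grp_lys_probe <- function(chain = "A", resseq = 1) {
  # CE-NZ along -x; ammonium hydrogens staggered anti to CE (tetrahedral)
  CE <- c(-1.49, 0, 0)
  hs <- t(vapply(0:2, function(j) {
    w <- as.numeric(rotate_about(matrix(c(0, 1, 0), 1), c(1, 0, 0), 120 * j))
    th <- (180 - 109.5) * pi / 180
    1.01 * (cos(th) * c(1, 0, 0) + sin(th) * w)
  }, numeric(3)))
  mk_atoms(c("CE", "NZ", "HZ1", "HZ2", "HZ3"), c("C", "N", "H", "H", "H"),
           rbind(CE, c(0, 0, 0), hs), "LYS", chain, resseq)
}

grp_asp_probe <- function(chain = "A", resseq = 1) {
  a <- 63 * pi / 180
  mk_atoms(c("CB", "CG", "OD1", "OD2"), c("C", "C", "O", "O"),
           rbind(c(-1.52, 0, 0), c(0, 0, 0),
                 1.25 * c(cos(a), sin(a), 0), 1.25 * c(cos(a), -sin(a), 0)),
           "ASP", chain, resseq)
}

grp_chloromethane <- function(chain = "L", resseq = 1, element = "Cl") {
  mk_atoms(c("C1", "X1"), c("C", element),
           rbind(c(-1.77, 0, 0), c(0, 0, 0)),
           "UNL", chain, resseq, hetero = TRUE)
}

# planar nucleobase in z = 0, 6-ring centroid at origin; includes donor
# hydrogens (in-plane) and the glycosidic C1'
nucleobase_atoms <- function(base, chain = "L", resseq = 1, hetero = FALSE) {
  hex_names <- c("N1", "C2", "N3", "C4", "C5", "C6")
  hx <- hexagon(1.38)
  coords <- stats::setNames(lapply(seq_len(6), function(i) hx[i, ]), hex_names)
  out_dir <- function(at) unit(coords[[at]])
  add <- function(lst, name, pos) { lst[[name]] <- pos; lst }
  purine <- base %in% c("A", "G", "DA", "DG")
  if (purine) {
    # fuse the 5-ring on the C4-C5 edge, pointing away from the hexagon
    m <- (coords$C4 + coords$C5) / 2
    outv <- unit(m)
    s <- 1.38
    R5 <- s / (2 * sin(36 * pi / 180))
    ctr5 <- m + outv * R5 * cos(36 * pi / 180)
    ang <- function(p) atan2(p[2] - ctr5[2], p[1] - ctr5[1])
    a4 <- ang(coords$C4); a5 <- ang(coords$C5)
    # step around the pentagon starting after C5, away from C4
    step <- 72 * pi / 180
    dirn <- if (sin(a5 - a4) > 0) 1 else -1
    p <- a5
    for (nm in c("N7", "C8", "N9")) {
      p <- p + dirn * step
      coords <- add(coords, nm, ctr5 + R5 * c(cos(p), sin(p), 0))
    }
  }
  h_at <- function(from, to_dir, bl = 1.01) from + bl * to_dir
  if (base %in% c("G", "DG")) {
    coords <- add(coords, "O6", coords$C6 + 1.23 * out_dir("C6"))
    coords <- add(coords, "N2", coords$C2 + 1.34 * out_dir("C2"))
    coords <- add(coords, "H1", h_at(coords$N1, out_dir("N1")))
    n2dir <- unit(coords$N2 - coords$C2)
    side <- pracma_cross(c(0, 0, 1), n2dir)
    coords <- add(coords, "H21", coords$N2 + 1.01 * unit(n2dir + 0.8 * side))
    coords <- add(coords, "H22", coords$N2 + 1.01 * unit(n2dir - 0.8 * side))
    glyc <- "N9"
  } else if (base %in% c("A", "DA")) {
    coords <- add(coords, "N6", coords$C6 + 1.34 * out_dir("C6"))
    n6dir <- unit(coords$N6 - coords$C6)
    side <- pracma_cross(c(0, 0, 1), n6dir)
    coords <- add(coords, "H61", coords$N6 + 1.01 * unit(n6dir + 0.8 * side))
    coords <- add(coords, "H62", coords$N6 + 1.01 * unit(n6dir - 0.8 * side))
    glyc <- "N9"
  } else if (base %in% c("C", "DC")) {
    coords <- add(coords, "O2", coords$C2 + 1.23 * out_dir("C2"))
    coords <- add(coords, "N4", coords$C4 + 1.34 * out_dir("C4"))
    n4dir <- unit(coords$N4 - coords$C4)
    side <- pracma_cross(c(0, 0, 1), n4dir)
    coords <- add(coords, "H41", coords$N4 + 1.01 * unit(n4dir + 0.8 * side))
    coords <- add(coords, "H42", coords$N4 + 1.01 * unit(n4dir - 0.8 * side))
    glyc <- "N1"
  } else {  # U / DT
    coords <- add(coords, "O2", coords$C2 + 1.23 * out_dir("C2"))
    coords <- add(coords, "O4", coords$C4 + 1.23 * out_dir("C4"))
    coords <- add(coords, "H3", h_at(coords$N3, out_dir("N3")))
    if (base == "DT")
      coords <- add(coords, "C7", coords$C5 + 1.50 * out_dir("C5"))
    glyc <- "N1"
  }
  coords <- add(coords, "C1'", coords[[glyc]] + 1.47 * out_dir(glyc))
  nm <- names(coords)
  el <- ifelse(grepl("^H", nm), "H", substr(nm, 1, 1))
  mk_atoms(nm, el, do.call(rbind, coords), base, chain, resseq,
           hetero = hetero)
}

#' Describe a planted interaction for the fixture generator
#'
#' @param type one of the interaction types (see `INTERACTION_TYPES`), e.g.
#'   `"hbond"`, `"pistacking"`
#' @param ... geometry parameters understood by the planter for that type
#'   (`dist`, `angle`, `offset`, `d1`, `d2`, `omega`, `don_angle`,
#'   `acc_angle`, `n_coord`, `donor`, `cation`, `face_on`, `tshape`,
#'   `nucleic`, `element`)
#' @return a plant specification (list) consumed by [generate_fixture()]
#' @export
plant <- function(type, ...) {
  stopifnot(type %in% INTERACTION_TYPES)
  structure(list(type = type, params = list(...)), class = "nci_plant")
}

solve_hbond_acceptor <- function(dpos, hpos, dist, angle) {
  # acceptor position in the xz-plane of the donor frame with the requested
  # D...A distance and D-H...A angle
  f <- function(alpha) {
    a <- dpos + dist * c(sin(alpha), 0, cos(alpha))
    angle3(dpos, hpos, a) - angle
  }
  alpha <- stats::uniroot(f, c(1e-6, pi - 1e-6), tol = 1e-10)$root
  dpos + dist * c(sin(alpha), 0, cos(alpha))
}

# Snap a fixture's critical geometry back onto the requested value after
# PDB 3-decimal rounding, from the safe side of an inclusive threshold:
# dir = -1 keeps the measured value at or below the target, +1 at or above.
snap_spec <- function(kind, move, ref, target, dir, vertex = NULL,
                      meas = NULL) {
  list(kind = kind, move = move, ref = ref, target = target, dir = dir,
       vertex = vertex, meas = if (is.null(meas)) move else meas)
}

apply_snap <- function(atoms, idx, sn) {
  sel_move <- atoms$arrangement == idx & atoms$tag %in% sn$move
  pt_of <- function(tags) {
    sel <- atoms$arrangement == idx & atoms$tag %in% tags
    colMeans(as.matrix(atoms[sel, c("x", "y", "z"), drop = FALSE]))
  }
  for (iter in 1:25) {
    if (sn$kind == "dist") {
      r <- pt_of(sn$ref)
      m <- pt_of(sn$meas)
      d <- dist3(m, r)
      if ((sn$dir < 0 && d <= sn$target) || (sn$dir > 0 && d >= sn$target))
        break
      shift <- (r + (m - r) * (sn$target + sn$dir * 2e-3) / d) - m
      atoms[sel_move, c("x", "y", "z")] <-
        sweep(as.matrix(atoms[sel_move, c("x", "y", "z"), drop = FALSE]),
              2, shift, "+")
    } else {  # angle at vertex between ref and move
      v <- pt_of(sn$vertex)
      a <- angle3(pt_of(sn$ref), v, pt_of(sn$meas))
      if ((sn$dir < 0 && a <= sn$target) || (sn$dir > 0 && a >= sn$target))
        break
      axis <- pracma_cross(pt_of(sn$ref) - v, pt_of(sn$meas) - v)
      if (vnorm(axis) < 1e-9) break
      rot <- sn$target + sn$dir * 5e-2 - a
      pts <- sweep(as.matrix(atoms[sel_move, c("x", "y", "z"), drop = FALSE]),
                   2, v)
      pts <- rotate_about(pts, unit(axis), rot)
      atoms[sel_move, c("x", "y", "z")] <- sweep(pts, 2, v, "+")
    }
    atoms$x <- round(atoms$x, 3); atoms$y <- round(atoms$y, 3)
    atoms$z <- round(atoms$z, 3)
  }
  atoms
}

# Each planter returns list(lig, rec, wat, expected, snaps); `expected` rows
# refer to atoms by tag, mapped to serials after assembly.
planter <- function(type, params, rec_resseq, lig_resseq) {
  p <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default
  expected <- list()
  snaps <- list()
  wat <- NULL
  nucleic_mode <- FALSE

  if (type == "hydrophobic") {
    dist <- p("dist", 3.8)
    lig <- mk_atoms("C1", "C", c(0, 0, 0), "UNL", "L", lig_resseq, hetero = TRUE)
    rec <- mk_atoms("CB", "C", c(dist, 0, 0), "ALA", "A", rec_resseq)
    expected <- list(list(type = type, expect = dist <= 4.0,
                          lig_tags = "C1", rec_tags = "CB"))
  } else if (type == "hbond") {
    dist <- p("dist", 2.9); ang <- p("angle", 165)
    donor <- p("donor", "ligand"); nuc <- p("nucleic", FALSE)
    if (donor == "ligand" && !nuc) {
      lig <- grp_formamide_donor("L", lig_resseq)
      A <- solve_hbond_acceptor(c(0, 0, 0), c(0, 0, 1.01), dist, ang)
      Y <- A + 1.23 * unit(A - c(0, 0, 1.01))
      rec <- mk_atoms(c("O", "C"), c("O", "C"), rbind(A, Y), "ALA", "A",
                      rec_resseq)
      expected <- list(list(type = type, expect = dist <= 4.1 && ang >= 100,
                            lig_tags = "N1", rec_tags = "O"))
      snaps <- list(snap_spec("dist", "O", "N1", dist, -1))
      if (ang <= 100.5)
        snaps <- c(snaps, list(snap_spec("angle", "O", "N1", ang, 1,
                                         vertex = "H1")))
    } else if (donor == "ligand" && nuc) {
      # uracil imide N3-H as the nucleic donor (its flanking O2/O4 are
      # acceptors, so no competing donor reaches the planted acceptor)
      lig <- nucleobase_atoms("U", "L", lig_resseq)
      n3 <- as.numeric(lig[lig$name == "N3", c("x", "y", "z")])
      h3 <- as.numeric(lig[lig$name == "H3", c("x", "y", "z")])
      axis_z <- unit(h3 - n3)
      A_local <- solve_hbond_acceptor(c(0, 0, 0), c(0, 0, 1.01), dist, ang)
      ex <- perp_unit(axis_z)
      R <- cbind(ex, pracma_cross(axis_z, ex), axis_z)
      A <- n3 + as.numeric(R %*% A_local)
      Y <- A + 1.23 * unit(A - h3)
      rec <- mk_atoms(c("O", "C"), c("O", "C"), rbind(A, Y), "ALA", "A",
                      rec_resseq)
      expected <- list(list(type = type, expect = dist <= 4.1 && ang >= 100,
                            lig_tags = "N3", rec_tags = "O"))
      snaps <- list(snap_spec("dist", "O", "N3", dist, -1))
      if (ang <= 100.5)
        snaps <- c(snaps, list(snap_spec("angle", "O", "N3", ang, 1,
                                         vertex = "H3")))
    } else {
      # receptor donor (Ser OG-HG), ligand acceptor (formamide O)
      rec <- mk_atoms(c("CB", "OG", "HG"), c("C", "O", "H"),
                      rbind(c(1.348, 0, -0.478), c(0, 0, 0), c(0, 0, 0.96)),
                      "SER", "A", rec_resseq)
      A <- solve_hbond_acceptor(c(0, 0, 0), c(0, 0, 0.96), dist, ang)
      C1 <- A + 1.23 * unit(A - c(0, 0, 0.96))
      N1 <- C1 + 1.33 * unit(A - c(0, 0, 0.96))
      lig <- mk_atoms(c("O1", "C1", "N1"), c("O", "C", "N"),
                      rbind(A, C1, N1), "UNL", "L", lig_resseq, hetero = TRUE)
      expected <- list(list(type = type, expect = dist <= 4.1 && ang >= 100,
                            lig_tags = "O1", rec_tags = "OG"))
      snaps <- list(snap_spec("dist", "O1", "OG", dist, -1))
      if (ang <= 100.5)
        snaps <- c(snaps, list(snap_spec("angle", "O1", "OG", ang, 1,
                                         vertex = "HG")))
    }
  } else if (type == "waterbridge") {
    d1 <- p("d1", 2.8); d2 <- p("d2", 2.8); om <- p("omega", 110)
    wat <- grp_water("W", lig_resseq + 500)
    O1 <- c(d1, 0, 0)
    lig <- mk_atoms(c("O1", "C1", "N1"), c("O", "C", "N"),
                    rbind(O1, O1 + c(1.23, 0, 0), O1 + c(2.56, 0, 0)),
                    "UNL", "L", lig_resseq, hetero = TRUE)
    og <- d2 * c(cos(om * pi / 180), sin(om * pi / 180), 0)
    hg <- og + 0.96 * unit(-og)    # O-H pointing at the water
    cb <- og + 1.43 * unit(c(-og[2], og[1], 0))
    rec <- mk_atoms(c("OG", "HG", "CB"), c("O", "H", "C"),
                    rbind(og, hg, cb), "SER", "A", rec_resseq)
    ok <- d1 >= 2.5 && d1 <= 4.1 && d2 >= 2.5 && d2 <= 4.1 &&
      om >= 75 && om <= 140
    expected <- list(list(type = type, expect = ok,
                          lig_tags = "O1", rec_tags = "OG", water_tag = "O"))
    snaps <- list(
      snap_spec("dist", "O1", "O", d1, if (d1 <= 3.3) 1 else -1),
      snap_spec("dist", c("OG", "HG", "CB"), "O", d2,
                if (d2 <= 3.3) 1 else -1, meas = "OG"),
      snap_spec("angle", c("OG", "HG", "CB"), "O1", om,
                if (om <= 107) 1 else -1, vertex = "O", meas = "OG"))
  } else if (type == "saltbridge") {
    dist <- p("dist", 4.0); lig_sign <- p("lig_sign", "negative")
    if (lig_sign == "negative") {
      lig <- grp_acetate("L", lig_resseq)           # neg centroid at +x
      ctr <- (as.numeric(lig[lig$name == "O1", c("x", "y", "z")]) +
                as.numeric(lig[lig$name == "O2", c("x", "y", "z")])) / 2
      rec <- shift_atoms(grp_lys_probe("A", rec_resseq), ctr + c(dist, 0, 0))
      expected <- list(list(type = type, expect = dist <= 5.5,
                            lig_tags = c("O1", "O2"), rec_tags = "NZ"))
      snaps <- list(snap_spec("dist", c("CE", "NZ", "HZ1", "HZ2", "HZ3"),
                              c("O1", "O2"), dist, -1, meas = "NZ"))
    } else {
      lig <- grp_ammonium("L", lig_resseq)
      rec <- grp_asp_probe("A", rec_resseq)
      ctr <- (as.numeric(rec[rec$name == "OD1", c("x", "y", "z")]) +
                as.numeric(rec[rec$name == "OD2", c("x", "y", "z")])) / 2
      rec <- shift_atoms(rec, c(dist, 0, 0) - ctr)
      expected <- list(list(type = type, expect = dist <= 5.5,
                            lig_tags = "N1", rec_tags = c("OD1", "OD2")))
      snaps <- list(snap_spec("dist", c("CB", "CG", "OD1", "OD2"),
                              "N1", dist, -1, meas = c("OD1", "OD2")))
    }
  } else if (type == "pistacking") {
    dist <- p("dist", 4.3); ang <- p("angle", 0); off <- p("offset", 0.5)
    tshape <- p("tshape", FALSE)
    lig <- grp_benzene("UNL", "L", lig_resseq)
    rec <- grp_phe_ring("A", rec_resseq)
    rec <- rotate_atoms(rec, c(0, 0, 1), 30)     # interleave carbons
    if (tshape) {
      rec <- rotate_atoms(rec, c(1, 0, 0), 90)
      rec <- shift_atoms(rec, c(off, 0, sqrt(dist^2 - off^2)))
    } else {
      if (ang != 0) rec <- rotate_atoms(rec, c(1, 0, 0), ang)
      rec <- shift_atoms(rec, c(off, 0, sqrt(dist^2 - off^2)))
    }
    fold <- min(ang %% 180, 180 - ang %% 180)
    eff_ang <- if (tshape) 90 else fold
    ok <- dist <= 5.5 && off <= 2.0 &&
      (eff_ang <= 30 || eff_ang >= 60)
    expected <- list(list(type = type, expect = ok,
                          lig_tags = paste0("C", 1:6),
                          rec_tags = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")))
  } else if (type == "pication") {
    dist <- p("dist", 4.0); face_on <- p("face_on", TRUE)
    cation <- p("cation", "guanidinium")
    if (cation == "guanidinium") {
      lig <- grp_benzene("UNL", "L", lig_resseq)      # ring in z = 0
      rec <- grp_arg_guanidinium("A", rec_resseq)
      ctr_shift <- if (face_on) c(0, 0, dist) else c(dist, 0, 0)
      rec <- shift_atoms(rec, ctr_shift)
      ok <- dist <= 6.0 && face_on
      expected <- list(list(type = type, expect = ok,
                            lig_tags = paste0("C", 1:6),
                            rec_tags = c("CZ", "NE", "NH1", "NH2")))
    } else {
      lig <- grp_ammonium("L", lig_resseq)
      rec <- shift_atoms(grp_phe_ring("A", rec_resseq), c(0, 0, -dist))
      ok <- dist <= 6.0
      expected <- list(list(type = type, expect = ok,
                            lig_tags = "N1",
                            rec_tags = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")))
    }
  } else if (type == "halogen") {
    dist <- p("dist", 3.3); da <- p("don_angle", 170); aa <- p("acc_angle", 120)
    nuc <- p("nucleic", FALSE); element <- p("element", "Cl")
    lig <- grp_chloromethane("L", lig_resseq, element)
    phi <- (180 - da) * pi / 180
    A <- dist * c(cos(phi), sin(phi), 0)
    dir_ax <- unit(c(0, 0, 0) - A)
    ydir <- as.numeric(rotate_about(matrix(dir_ax, 1), c(0, 0, 1), aa))
    if (nuc) {
      nucleic_mode <- TRUE
      Y <- A + 1.60 * ydir
      op2 <- Y + 1.48 * unit(Y - A)
      o5p <- Y + 1.60 * c(0, 0, 1)
      rec <- mk_atoms(c("OP1", "P", "OP2", "O5'"), c("O", "P", "O", "O"),
                      rbind(A, Y, op2, o5p), "DG", "B", rec_resseq)
      a_tag <- "OP1"
    } else {
      Y <- A + 1.23 * ydir
      rec <- mk_atoms(c("O", "C"), c("O", "C"), rbind(A, Y), "ALA", "A",
                      rec_resseq)
      a_tag <- "O"
    }
    ok <- dist <= 4.0 && abs(da - 165) <= 30 && abs(aa - 120) <= 30 &&
      element != "F"
    expected <- list(list(type = type, expect = ok,
                          lig_tags = "X1", rec_tags = a_tag))
    snaps <- list(snap_spec("dist", a_tag, "X1", dist, -1))
  } else if (type == "metal") {
    dist <- p("dist", 2.1); n <- p("n_coord", 6); element <- p("element", "MG")
    lig <- mk_atoms(element, norm_element(element), c(0, 0, 0), element,
                    "L", lig_resseq, hetero = TRUE)
    dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
    # Asp carboxylate with OD1 pointing at the metal, rest trans (outside
    # the coordination shell)
    od1 <- c(dist, 0, 0)
    cg <- od1 + c(1.25, 0, 0)
    od2 <- cg + 1.25 * c(0.45, 0.893, 0)
    cb <- cg + 1.52 * c(0.45, -0.893, 0)
    rec <- mk_atoms(c("OD1", "CG", "OD2", "CB"), c("O", "C", "O", "C"),
                    rbind(od1, cg, od2, cb), "ASP", "A", rec_resseq)
    wat_list <- list()
    tags <- "OD1"
    if (n > 1) for (j in 2:min(n, 6)) {
      w <- shift_atoms(grp_water("W", lig_resseq + 500 + j), dist * dirs[j, ])
      w$tag <- paste0("O_w", j)
      wat_list[[length(wat_list) + 1]] <- w
      tags <- c(tags, paste0("O_w", j))
    }
    wat <- if (length(wat_list)) do.call(rbind, wat_list) else NULL
    geom <- if (n >= 6) "octahedral" else if (n == 1) "other/underdetermined"
            else NA_character_
    expected <- list(list(type = type, expect = dist <= 3.0,
                          lig_tags = lig$tag[1], rec_tags = tags,
                          n_coord = min(n, 6), geom = geom))
  } else {
    stop(sprintf("no planter for interaction type '%s'", type))
  }
  list(lig = lig, rec = rec, wat = wat, expected = expected,
       snaps = snaps, nucleic_mode = nucleic_mode)
}

measure_planted <- function(type, atoms, lig_serials, rec_serials,
                            water_serial = NA) {
  xyz <- function(ser) {
    m <- atoms[match(ser, atoms$serial), c("x", "y", "z"), drop = FALSE]
    if (nrow(m) == 1) as.numeric(m) else colMeans(as.matrix(m))
  }
  if (type %in% c("hydrophobic", "hbond", "saltbridge", "pication",
                  "halogen", "metal")) {
    lig_pt <- if (type == "metal") xyz(lig_serials[1]) else xyz(lig_serials)
    rec_pt <- if (type == "metal") xyz(rec_serials[1]) else xyz(rec_serials)
    return(c(dist = dist3(lig_pt, rec_pt)))
  }
  if (type == "waterbridge") {
    w <- xyz(water_serial)
    return(c(dist = dist3(xyz(lig_serials), w),
             dist2 = dist3(xyz(rec_serials), w),
             angle = angle3(xyz(lig_serials), w, xyz(rec_serials))))
  }
  if (type == "pistacking") {
    lp <- fit_plane(t(vapply(lig_serials, xyz, numeric(3))))
    rp <- fit_plane(t(vapply(rec_serials, xyz, numeric(3))))
    off <- min(plane_offset(rp$centroid, lp$centroid, lp$normal),
               plane_offset(lp$centroid, rp$centroid, rp$normal))
    return(c(dist = dist3(lp$centroid, rp$centroid),
             angle = plane_angle(lp$normal, rp$normal), offset = off))
  }
  c(dist = NA_real_)
}

#' Generate a synthetic PDB fixture with planted interactions
#'
#' Assembles the requested arrangements on a 30 A grid (so arrangements
#' cannot interact with each other), adds decoy atoms, optionally applies
#' seeded coordinate jitter, rounds to PDB precision and writes the file
#' plus a tab-separated ground-truth manifest (`<path>.manifest.tsv`).
#'
#' @param spec list of [plant()] specifications
#' @param path output PDB path
#' @param seed integer seed driving the (optional) jitter
#' @param jitter uniform per-coordinate jitter amplitude in Angstrom
#'   (at most 0.05; default 0 = byte-identical output across runs)
#' @param models number of MODEL blocks (each model is the same arrangement
#'   translated by +1 A in z per extra model)
#' @return an `nci_fixture`: `path`, `manifest` data frame (planted type,
#'   serials, measured geometry, expectation flag), `model_atom_counts`,
#'   `nucleic_mode` (whether the fixture needs the nucleic-receptor mode)
#' @export
generate_fixture <- function(spec, path, seed = 1L, jitter = 0, models = 1L) {
  stopifnot(jitter <= 0.05)
  if (inherits(spec, "nci_plant")) spec <- list(spec)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  all_atoms <- list()
  manifest <- list()
  snap_list <- list()
  nucleic_mode <- FALSE
  for (i in seq_along(spec)) {
    pl <- planter(spec[[i]]$type, spec[[i]]$params,
                  rec_resseq = 100 + i, lig_resseq = i)
    nucleic_mode <- nucleic_mode || pl$nucleic_mode
    snap_list[[i]] <- pl$snaps
    off <- c(30 * (i - 1), 0, 0)
    arr <- rbind(shift_atoms(pl$lig, off), shift_atoms(pl$rec, off),
                 if (!is.null(pl$wat)) shift_atoms(pl$wat, off))
    arr$arrangement <- i
    all_atoms[[i]] <- arr
    for (e in pl$expected) manifest[[length(manifest) + 1]] <- c(e, idx = i)
  }
  # decoys, far from every arrangement
  decoy <- rbind(
    mk_atoms("CD1", "C", c(-20, 50, 0), "ILE", "A", 999),
    mk_atoms("O", "O", c(-20, 60, 0), "HOH", "W", 998))
  decoy$arrangement <- 0L
  all_atoms[[length(all_atoms) + 1]] <- decoy
  atoms <- do.call(rbind, all_atoms)

  if (jitter > 0) {
    n <- nrow(atoms)
    atoms$x <- atoms$x + stats::runif(n, -jitter, jitter)
    atoms$y <- atoms$y + stats::runif(n, -jitter, jitter)
    atoms$z <- atoms$z + stats::runif(n, -jitter, jitter)
  }
  atoms$x <- round(atoms$x, 3); atoms$y <- round(atoms$y, 3)
  atoms$z <- round(atoms$z, 3)
  for (pass in 1:2) for (i in seq_along(spec)) {
    for (sn in snap_list[[i]]) atoms <- apply_snap(atoms, i, sn)
  }

  # infeasibility check: no two heavy atoms of one arrangement may overlap
  heavy <- atoms[atoms$element != "H", , drop = FALSE]
  for (i in unique(heavy$arrangement)) {
    h <- heavy[heavy$arrangement == i, , drop = FALSE]
    if (nrow(h) < 2) next
    d <- cross_dist(as.matrix(h[, c("x", "y", "z")]),
                    as.matrix(h[, c("x", "y", "z")]))
    diag(d) <- Inf
    if (min(d) < 0.8)
      stop(sprintf("geometrically infeasible spec: overlapping atoms in arrangement %d (min distance %.2f A)",
                   i, min(d)))
  }

  atoms$serial <- seq_len(nrow(atoms))
  # replicate into extra models, shifted so models differ
  full <- atoms
  if (models > 1) {
    full$model <- 1L
    base_n <- nrow(atoms)
    for (m in 2:models) {
      am <- atoms
      am$z <- round(am$z + (m - 1), 3)
      am$serial <- am$serial + base_n * (m - 1)
      am$model <- m
      full <- rbind(full, am)
    }
  } else {
    full$model <- 1L
  }

  s <- structure(list(
    atoms = full[, c("serial", "name", "altloc", "resname", "chain", "resseq",
                     "icode", "x", "y", "z", "occ", "element", "hetero",
                     "model")],
    conect = data.frame(from = integer(0), to = integer(0)),
    nmodels = as.integer(models), selected_model = 1L,
    header_id = NA_character_), class = "nci_structure")
  write_pdb(s, path)

  # manifest rows with serial mapping and post-rounding measured geometry
  tag_serial <- function(idx, tags, pool = atoms) {
    vapply(tags, function(tg) {
      hit <- pool$serial[pool$arrangement == idx & pool$tag == tg]
      hit[1]
    }, numeric(1))
  }
  mrows <- lapply(manifest, function(e) {
    ls <- tag_serial(e$idx, e$lig_tags)
    rs <- tag_serial(e$idx, e$rec_tags)
    ws <- if (!is.null(e$water_tag)) {
      pool <- atoms[atoms$arrangement == e$idx & atoms$tag == e$water_tag, ]
      pool$serial[1]
    } else NA
    g <- measure_planted(e$type, atoms, ls, rs, ws)
    data.frame(idx = e$idx, type = e$type, expect = e$expect,
               lig_serials = paste(sort(ls), collapse = ","),
               rec_serials = paste(sort(rs), collapse = ","),
               water_serial = ifelse(is.na(ws), NA_integer_, as.integer(ws)),
               dist = unname(g["dist"]),
               dist2 = unname(ifelse(is.na(g["dist2"]), NA, g["dist2"])),
               angle = unname(ifelse(is.na(g["angle"]), NA, g["angle"])),
               offset = unname(ifelse(is.na(g["offset"]), NA, g["offset"])),
               n_coord = ifelse(is.null(e$n_coord), NA_integer_, e$n_coord),
               geom = ifelse(is.null(e$geom), NA_character_, e$geom),
               stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, mrows)
  utils::write.table(man, paste0(path, ".manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  structure(list(path = path, manifest = man,
                 model_atom_counts = rep(nrow(atoms), models),
                 nucleic_mode = nucleic_mode),
            class = "nci_fixture")
}

#' The standard boundary-behaviour fixture suite
#'
#' Three arrangements per interaction class: inside the default thresholds,
#' exactly at a threshold (inclusive bounds: must be reported) and outside.
#'
#' @return named list of [plant()] specifications
#' @export
standard_fixture_specs <- function() {
  list(
    hydrophobic_inside = plant("hydrophobic", dist = 3.8),
    hydrophobic_boundary = plant("hydrophobic", dist = 4.0),
    hydrophobic_outside = plant("hydrophobic", dist = 4.2),
    hbond_inside = plant("hbond", dist = 2.9, angle = 165),
    hbond_boundary_dist = plant("hbond", dist = 4.1, angle = 165),
    hbond_boundary_angle = plant("hbond", dist = 2.9, angle = 100),
    hbond_outside_angle = plant("hbond", dist = 2.9, angle = 80),
    hbond_outside_dist = plant("hbond", dist = 4.3, angle = 165),
    hbond_receptor_donor = plant("hbond", dist = 3.0, angle = 160,
                                 donor = "receptor"),
    hbond_nucleic_ligand = plant("hbond", dist = 2.9, angle = 160,
                                 nucleic = TRUE),
    waterbridge_inside = plant("waterbridge", d1 = 2.8, d2 = 2.8, omega = 110),
    waterbridge_boundary = plant("waterbridge", d1 = 2.5, d2 = 4.1,
                                 omega = 140),
    waterbridge_outside = plant("waterbridge", d1 = 4.5, d2 = 2.8,
                                omega = 110),
    saltbridge_inside = plant("saltbridge", dist = 4.0),
    saltbridge_boundary = plant("saltbridge", dist = 5.5,
                                lig_sign = "positive"),
    saltbridge_outside = plant("saltbridge", dist = 6.0),
    pistacking_inside = plant("pistacking", dist = 4.3, angle = 0,
                              offset = 0.5),
    pistacking_tshape = plant("pistacking", dist = 5.2, angle = 0,
                              offset = 0, tshape = TRUE),
    pistacking_boundary = plant("pistacking", dist = 5.5, angle = 0,
                                offset = 0),
    pistacking_outside = plant("pistacking", dist = 5.4, angle = 45,
                               offset = 0),
    pication_inside = plant("pication", dist = 4.0, face_on = TRUE),
    pication_boundary = plant("pication", dist = 6.0, cation = "ammonium"),
    pication_outside = plant("pication", dist = 5.0, face_on = FALSE),
    halogen_inside = plant("halogen", dist = 3.3, don_angle = 170,
                           acc_angle = 120),
    halogen_boundary = plant("halogen", dist = 4.0, don_angle = 165,
                             acc_angle = 120),
    halogen_outside = plant("halogen", dist = 3.3, don_angle = 120,
                            acc_angle = 120),
    halogen_nucleic = plant("halogen", dist = 3.4, don_angle = 170,
                            acc_angle = 115, nucleic = TRUE, element = "Br"),
    metal_inside = plant("metal", dist = 2.1, n_coord = 6),
    metal_boundary = plant("metal", dist = 3.0, n_coord = 1),
    metal_outside = plant("metal", dist = 3.4, n_coord = 1, element = "ZN")
  )
}
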