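#' @title Synthetic integration complexes
#'
#' @description
#' Two hand-built synthetic complexes that emulate, at desk scale, the
#' qualitative interaction patterns of well-known experimental systems.
#' They are constructed from idealised chemical groups, not downloaded
#' coordinates, and are named synthetic throughout.
#'
#' * `synthetic_rna_protein_complex()`: an RNA 5-mer (UGGUG) bound by a
#'   minimal protein pocket - an aromatic side chain intercalated between
#'   the two central guanine bases (parallel pi-stacks), an arginine
#'   guanidinium face-on under one guanine (pi-cation), a lysine ammonium
#'   next to a backbone phosphate (salt bridge), plus hydrogen-bond and
#'   hydrophobic partners. Run with the default mode, the RNA chain is the
#'   ligand entity.
#'
#' * `synthetic_elongation_complex()`: a nucleoside-triphosphate ligand in
#'   a transcription-like pocket: its guanine pairs with a DNA cytosine
#'   (three Watson-Crick hydrogen bonds, chain T), stacks on an RNA guanine
#'   and donates one hydrogen bond to an RNA adenine (chain R), while the
#'   triphosphate tail forms a salt bridge with a lysine and a magnesium
#'   ion nearby is octahedrally coordinated by protein carboxylates and
#'   waters. Run with the nucleic-receptor mode.
#'
#' @name synthetic-complexes
NULL

place_base <- function(base, center, azimuth = 0, z = 0, chain, resseq,
                       resname = base, hetero = FALSE, flip = FALSE) {
  b <- nucleobase_atoms(base, chain, resseq, hetero)
  b$resname <- resname
  if (flip) b$z <- -b$z
  if (azimuth != 0) b <- rotate_atoms(b, c(0, 0, 1), azimuth)
  shift_atoms(b, c(center[1], center[2], z))
}

base_xyz <- function(atoms, name) {
  as.numeric(atoms[atoms$name == name, c("x", "y", "z")][1, ])
}

finish_synthetic <- function(groups, path) {
  atoms <- do.call(rbind, groups)
  atoms$x <- round(atoms$x, 3); atoms$y <- round(atoms$y, 3)
  atoms$z <- round(atoms$z, 3)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$model <- 1L
  s <- structure(list(
    atoms = atoms[, c("serial", "name", "altloc", "resname", "chain",
                      "resseq", "icode", "x", "y", "z", "occ", "element",
                      "hetero", "model")],
    conect = data.frame(from = integer(0), to = integer(0)),
    nmodels = 1L, selected_model = 1L, header_id = NA_character_),
    class = "nci_structure")
  write_pdb(s, path)
  invisible(path)
}

#' Synthetic RNA-protein recognition complex (UGGUG ligand)
#'
#' @param path output PDB path
#' @return the path, invisibly; analyse with the default mode (RNA as ligand)
#' @export
synthetic_rna_protein_complex <- function(path) {
  groups <- list()

  # central guanine G2: 6-ring centroid at origin, plane z = 0
  g2 <- place_base("G", c(0, 0), 0, 0, "R", 2)
  groups$g2 <- g2
  # G2 backbone phosphate, trailing off the glycosidic side
  c1p <- base_xyz(g2, "C1'")
  n9 <- base_xyz(g2, "N9")
  dirL <- unit(c1p - n9)
  p <- c1p + 1.9 * dirL
  groups$g2p <- mk_atoms(c("P", "OP1", "OP2"), c("P", "O", "O"),
                         rbind(p, p + 1.48 * unit(dirL + c(0, 0, 0.9)),
                               p + 1.48 * unit(dirL + c(0, 0, -0.9))),
                         "G", "R", 2)

  # aromatic side chain intercalated: parallel ring 3.8 A above G2,
  # and G3 another 3.8 A above it (stack sandwich)
  phe <- rotate_atoms(grp_phe_ring("A", 438), c(0, 0, 1), 30)
  groups$phe <- shift_atoms(phe, c(0, 0, 3.8))
  groups$g3 <- place_base("G", c(0, 0), 0, 7.6, "R", 3)

  # guanidinium face-on 4.0 A under the G2 6-ring
  groups$arg <- shift_atoms(grp_arg_guanidinium("A", 422), c(0, 0, -4.0))

  # lysine ammonium 4.0 A from the phosphate's negative centroid
  # (the cationic salt-bridge partner of the backbone charge)
  opc <- (base_xyz(groups$g2p, "OP1") + base_xyz(groups$g2p, "OP2")) / 2
  lys <- grp_lys_probe("A", 425)
  ang <- atan2(dirL[2], dirL[1]) * 180 / pi
  lys <- rotate_atoms(lys, c(0, 0, 1), ang)
  groups$lys <- shift_atoms(lys, opc + 4.0 * dirL)

  # serine hydroxyl donating to G2 O6 (2.9 A, near-linear)
  o6 <- base_xyz(g2, "O6")
  c6 <- base_xyz(g2, "C6")
  d6 <- unit(o6 - c6)
  og <- o6 + 2.9 * d6
  groups$ser <- mk_atoms(c("OG", "HG", "CB"), c("O", "H", "C"),
                         rbind(og, og - 0.96 * d6,
                               og + 1.43 * unit(d6 + c(0, 0, 1))),
                         "SER", "A", 439)

  # U4 recognised by an asparagine amide (acceptor against the base N3-H)
  u4 <- place_base("U", c(0, -14), 0, 0, "R", 4)
  groups$u4 <- u4
  n3 <- base_xyz(u4, "N3"); h3 <- base_xyz(u4, "H3")
  d3 <- unit(h3 - n3)
  od1 <- n3 + 2.9 * d3
  cg <- od1 + 1.23 * d3
  nd2 <- cg + 1.34 * unit(d3 + c(0, 0, 1.2))
  groups$asn <- mk_atoms(c("OD1", "CG", "ND2"), c("O", "C", "N"),
                         rbind(od1, cg, nd2), "ASN", "A", 435)

  # U1 recognised hydrophobically (leucine methyl against the base C5)
  u1 <- place_base("U", c(0, 14), 0, 0, "R", 1)
  groups$u1 <- u1
  c5 <- base_xyz(u1, "C5")
  groups$leu <- mk_atoms("CD1", "C", c5 + c(0, 0, 3.8), "LEU", "A", 426)

  # G5: chain terminus without partners
  groups$g5 <- place_base("G", c(16, 8), 0, 0, "R", 5)

  finish_synthetic(groups, path)
}

#' Synthetic transcription elongation-like complex (NTP ligand)
#'
#' @param path output PDB path
#' @return the path, invisibly; analyse with
#'   `analysis_mode(nucleic_acids_as_receptor = TRUE)`
#' @export
synthetic_elongation_complex <- function(path) {
  groups <- list()

  # GTP guanine: 6-ring centroid at origin, plane z = 0 (HETATM, resname GTP)
  gua <- place_base("G", c(0, 0), 0, 0, "L", 900, resname = "GTP",
                    hetero = TRUE)
  groups$gua <- gua
  # sugar + triphosphate tail, descending out of the base plane
  c1p <- base_xyz(gua, "C1'")
  n9 <- base_xyz(gua, "N9")
  dxy <- unit(c1p - n9)
  dirL <- unit(c(dxy[1], dxy[2], 0) - c(0, 0, 0.55))
  tail_names <- c("C2'", "C3'", "C4'", "C5'", "O5'", "PA", "O1A", "O2A",
                  "O3A", "PB", "O1B", "O2B", "O3B", "PG", "O1G", "O2G", "O3G")
  tail_el <- c("C", "C", "C", "C", "O", "P", "O", "O", "O", "P", "O", "O",
               "O", "P", "O", "O", "O")
  pos <- c1p
  side <- unit(pracma_cross(dirL, c(0, 0, 1)))
  xyz <- matrix(0, length(tail_names), 3)
  for (i in seq_along(tail_names)) {
    nm <- tail_names[i]
    if (nm %in% c("O1A", "O2A", "O1B", "O2B", "O1G", "O2G")) {
      sgn <- if (nm %in% c("O1A", "O1B", "O1G")) 1 else -1
      xyz[i, ] <- pos + 1.48 * unit(sgn * side + c(0, 0, 0.35))
    } else {
      pos <- pos + 1.55 * dirL
      xyz[i, ] <- pos
    }
  }
  groups$tail <- mk_atoms(tail_names, tail_el, xyz, "GTP", "L", 900,
                          hetero = TRUE)

  # DNA cytosine (chain T) Watson-Crick paired to the guanine: rigid 2D fit
  # of the acceptor/donor triad to the three canonical bond distances
  dc_local <- nucleobase_atoms("DC", "T", 7)
  targets <- list(c("O6", "N4", 2.91), c("N1", "N3", 2.95), c("N2", "O2", 2.86))
  gpts <- lapply(targets, function(t) base_xyz(gua, t[1]))
  gua_heavy <- as.matrix(gua[gua$element != "H", c("x", "y", "z")])
  fit_one <- function(flip, theta0) {
    base0 <- dc_local
    if (flip) base0$z <- -base0$z
    obj <- function(par) {
      b <- rotate_atoms(base0, c(0, 0, 1), par[3])
      b <- shift_atoms(b, c(par[1], par[2], 0))
      resid <- sum(vapply(seq_along(targets), function(k) {
        (dist3(gpts[[k]], base_xyz(b, targets[[k]][2])) -
           as.numeric(targets[[k]][3]))^2
      }, numeric(1)))
      # keep the pairing non-overlapping: penalise heavy-atom clashes
      bh <- as.matrix(b[b$element != "H", c("x", "y", "z")])
      d <- cross_dist(bh, gua_heavy)
      resid + 10 * sum(pmax(0, 2.6 - d)^2)
    }
    fit <- stats::optim(c(6, 0, theta0), obj, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-12))
    list(fit = fit, flip = flip)
  }
  cand <- list()
  for (fl in c(FALSE, TRUE)) for (t0 in c(0, 90, 180, 270))
    cand[[length(cand) + 1]] <- fit_one(fl, t0)
  best <- cand[[which.min(vapply(cand, function(x) x$fit$value, numeric(1)))]]
  dc <- dc_local
  if (best$flip) dc$z <- -dc$z
  dc <- rotate_atoms(dc, c(0, 0, 1), best$fit$par[3])
  groups$dc <- shift_atoms(dc, c(best$fit$par[1], best$fit$par[2], 0))

  # RNA guanine (chain R) stacked in parallel 3.8 A below the GTP base
  groups$g10 <- place_base("G", c(0.8, 0), 30, -3.8, "R", 10)
  # RNA adenine accepting one hydrogen bond is implausible here - instead it
  # DONATES from N6 to the GTP N7 (Hoogsteen edge), in the base plane
  n7 <- base_xyz(gua, "N7")
  dir7 <- unit(c(n7[1], n7[2], 0))
  ade <- nucleobase_atoms("A", "R", 11)
  # rotate so the local C6->N6 direction points back at N7
  c6l <- base_xyz(ade, "C6"); n6l <- base_xyz(ade, "N6")
  loc_ang <- atan2(n6l[2] - c6l[2], n6l[1] - c6l[1]) * 180 / pi
  tgt_ang <- atan2(-dir7[2], -dir7[1]) * 180 / pi
  ade <- rotate_atoms(ade, c(0, 0, 1), tgt_ang - loc_ang)
  n6_now <- base_xyz(ade, "N6")
  groups$ade <- shift_atoms(ade, n7 + 2.90 * dir7 - n6_now)

  # lysine ammonium 4.0 A beyond the gamma-phosphate negative centroid
  og_ser <- groups$tail
  pg_oxy <- og_ser[og_ser$name %in% c("O1G", "O2G", "O3G"), c("x", "y", "z")]
  negc <- colMeans(as.matrix(pg_oxy))
  lys <- grp_lys_probe("P", 752)
  ang <- atan2(dirL[2], dirL[1]) * 180 / pi
  # aliphatic CE on the far side of the ammonium, clear of the phosphates
  lys <- rotate_atoms(lys, c(0, 0, 1), ang + 180)
  groups$lys <- shift_atoms(lys, negc + 4.0 * dirL)

  # magnesium octahedron off the phosphate tail: two protein carboxylates
  # and four waters at 2.1 A
  mg <- negc + c(0, 7.0, 0)
  groups$mg <- mk_atoms("MG", "Mg", mg, "MG", "M", 901, hetero = TRUE)
  od1 <- mg + c(2.1, 0, 0)
  cg <- od1 + c(1.25, 0, 0)
  groups$asp <- mk_atoms(c("OD1", "CG", "OD2", "CB"), c("O", "C", "O", "C"),
                         rbind(od1, cg, cg + 1.25 * c(0.45, 0.893, 0),
                               cg + 1.52 * c(0.45, -0.893, 0)),
                         "ASP", "P", 481)
  oe1 <- mg + c(-2.1, 0, 0)
  cd <- oe1 + c(-1.25, 0, 0)
  groups$glu <- mk_atoms(c("OE1", "CD", "OE2", "CG"), c("O", "C", "O", "C"),
                         rbind(oe1, cd, cd + 1.25 * c(-0.45, 0.893, 0),
                               cd + 1.52 * c(-0.45, -0.893, 0)),
                         "GLU", "P", 485)
  wdirs <- rbind(c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (j in 1:4) {
    w <- grp_water("W", 950 + j)
    groups[[paste0("w", j)]] <- shift_atoms(w, mg + 2.1 * wdirs[j, ])
  }

  finish_synthetic(groups, path)
}
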