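#' @title Rule-based interaction detection
#'
#' @description
#' Applies the geometric rules for the eight interaction classes against a
#' binding site, then refines the raw matches deterministically. Each
#' detector takes the perceived ligand-side and receptor-side features, the
#' atom table of the selected model (for coordinate lookup by serial) and a
#' threshold configuration. All distance/angle thresholds are inclusive.
#'
#' Interaction records are rows of one data frame; columns that do not apply
#' to a class are NA. Distances are Angstrom, angles unsigned degrees.
#'
#' @name interaction-detection
NULL

INTERACTION_TYPES <- c("hydrophobic", "hbond", "waterbridge", "saltbridge",
                       "pistacking", "pication", "halogen", "metal")

interaction_row <- function(type,
                            lig_serials, rec_serials,
                            lig_meta, rec_meta,
                            dist = NA_real_, dist2 = NA_real_,
                            angle = NA_real_, angle2 = NA_real_,
                            offset = NA_real_,
                            don_serial = NA_integer_, acc_serial = NA_integer_,
                            donor_side = NA_character_,
                            water_serial = NA_integer_,
                            geom_label = NA_character_,
                            coord_num = NA_integer_,
                            unverified = FALSE) {
  data.frame(
    type = type,
    lig_resname = lig_meta$resname, lig_chain = lig_meta$chain,
    lig_resseq = lig_meta$resseq, lig_icode = lig_meta$icode,
    rec_resname = rec_meta$resname, rec_chain = rec_meta$chain,
    rec_resseq = rec_meta$resseq, rec_icode = rec_meta$icode,
    lig_serials = paste(lig_serials, collapse = ","),
    rec_serials = paste(rec_serials, collapse = ","),
    dist = dist, dist2 = dist2, angle = angle, angle2 = angle2,
    offset = offset,
    don_serial = don_serial, acc_serial = acc_serial,
    donor_side = donor_side, water_serial = water_serial,
    geom_label = geom_label, coord_num = coord_num,
    unverified = unverified,
    receptor_is_nucleic = residue_kind(rec_meta$resname) %in% c("dna", "rna"),
    stringsAsFactors = FALSE
  )
}

empty_interactions <- function() {
  meta1 <- data.frame(resname = "X", chain = "A", resseq = 1L, icode = "",
                      stringsAsFactors = FALSE)
  interaction_row("hydrophobic", 1L, 1L, meta1, meta1)[0, , drop = FALSE]
}

coords_of <- function(atoms, serial) {
  as.numeric(atoms[match(serial, atoms$serial), c("x", "y", "z")])
}

meta_of_row <- function(df, i) {
  data.frame(resname = df$resname[i], chain = df$chain[i],
             resseq = df$resseq[i], icode = df$icode[i],
             stringsAsFactors = FALSE)
}

#' Detect hydrophobic contacts
#'
#' Carbon-carbon pairs between ligand and receptor hydrophobic atoms with a
#' distance at or below `hydroph_dist_max`, reduced deterministically: per
#' (ligand atom, receptor residue) only the closest pair survives, and any
#' fully connected contact cluster (every ligand atom of the cluster touching
#' every receptor atom) is reduced again to its single closest contact.
#' Ties break on the smaller distance, then the lower (receptor serial,
#' ligand serial).
#'
#' @param lf,rf ligand-side and receptor-side `nci_features`
#' @param atoms atom table of the selected model
#' @param cfg an `nci_config`
#' @return interaction data frame
#' @export
detect_hydrophobic <- function(lf, rf, atoms, cfg = default_config()) {
  out <- empty_interactions()
  la <- lf$hydrophobics; ra <- rf$hydrophobics
  if (!nrow(la) || !nrow(ra)) return(out)
  lc <- t(vapply(la$serial, coords_of, numeric(3), atoms = atoms))
  rc <- t(vapply(ra$serial, coords_of, numeric(3), atoms = atoms))
  d <- cross_dist(lc, rc)
  hits <- which(d <= cfg$hydroph_dist_max, arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(hits)), function(h) {
    i <- hits[h, 1]; j <- hits[h, 2]
    interaction_row("hydrophobic", la$serial[i], ra$serial[j],
                    meta_of_row(la, i), meta_of_row(ra, j),
                    dist = d[i, j])
  })
  raw <- if (length(rows)) do.call(rbind, rows) else out
  reduce_hydrophobic(raw)
}

# deterministic two-stage reduction of raw hydrophobic contacts
reduce_hydrophobic <- function(h) {
  if (!nrow(h)) return(h)
  ls <- as.integer(h$lig_serials)
  rs <- as.integer(h$rec_serials)
  ord <- order(h$dist, rs, ls)
  h <- h[ord, , drop = FALSE]; ls <- ls[ord]; rs <- rs[ord]
  # stage 1: closest contact per (ligand atom, receptor residue)
  key1 <- paste(ls, h$rec_chain, h$rec_resseq, h$rec_icode, h$rec_resname)
  keep <- !duplicated(key1)
  h <- h[keep, , drop = FALSE]; ls <- ls[keep]; rs <- rs[keep]
  # stage 2: fully connected clusters collapse to their closest contact
  nodes <- unique(c(paste0("L", ls), paste0("R", rs)))
  comp <- seq_along(nodes); names(comp) <- nodes
  for (i in seq_len(nrow(h))) {
    a <- match(paste0("L", ls[i]), nodes); b <- match(paste0("R", rs[i]), nodes)
    comp[comp == comp[b]] <- comp[a]
  }
  keep <- logical(nrow(h))
  for (cid in unique(comp)) {
    members <- nodes[comp == cid]
    lmem <- as.integer(sub("^L", "", members[startsWith(members, "L")]))
    rmem <- as.integer(sub("^R", "", members[startsWith(members, "R")]))
    in_comp <- ls %in% lmem & rs %in% rmem
    if (!any(in_comp)) next
    if (sum(in_comp) == length(lmem) * length(rmem) && sum(in_comp) > 1) {
      keep[which(in_comp)[1]] <- TRUE  # rows are distance-ordered
    } else {
      keep[in_comp] <- TRUE
    }
  }
  h <- h[keep, , drop = FALSE]
  rownames(h) <- NULL
  h
}

hbond_pairs_one_way <- function(don, acc, atoms, cfg, donor_side) {
  rows <- list()
  for (i in seq_len(nrow(don))) {
    d <- coords_of(atoms, don$serial[i])
    hs <- don$h_serials[[i]]
    for (j in seq_len(nrow(acc))) {
      if (acc$serial[j] == don$serial[i]) next
      a <- coords_of(atoms, acc$serial[j])
      dd <- dist3(d, a)
      if (dd > cfg$hbond_dist_max) next
      if (don$no_h[i] || !length(hs)) {
        # placement failed: distance-only, flagged lower-confidence
        lm <- if (donor_side == "ligand") meta_of_row(don, i) else meta_of_row(acc, j)
        rm <- if (donor_side == "ligand") meta_of_row(acc, j) else meta_of_row(don, i)
        lser <- if (donor_side == "ligand") don$serial[i] else acc$serial[j]
        rser <- if (donor_side == "ligand") acc$serial[j] else don$serial[i]
        rows[[length(rows) + 1]] <- interaction_row(
          "hbond", lser, rser, lm, rm, dist = dd,
          don_serial = don$serial[i], acc_serial = acc$serial[j],
          donor_side = donor_side, unverified = TRUE)
        next
      }
      # best hydrogen: largest D-H...A angle
      best <- NULL
      for (hser in hs) {
        hpos <- coords_of(atoms, hser)
        ang <- angle3(d, hpos, a)
        if (is.null(best) || ang > best$ang)
          best <- list(ang = ang, h = hpos)
      }
      if (best$ang < cfg$hbond_don_angle_min) next
      lm <- if (donor_side == "ligand") meta_of_row(don, i) else meta_of_row(acc, j)
      rm <- if (donor_side == "ligand") meta_of_row(acc, j) else meta_of_row(don, i)
      lser <- if (donor_side == "ligand") don$serial[i] else acc$serial[j]
      rser <- if (donor_side == "ligand") acc$serial[j] else don$serial[i]
      rows[[length(rows) + 1]] <- interaction_row(
        "hbond", lser, rser, lm, rm,
        dist = dd, dist2 = dist3(best$h, a), angle = best$ang,
        don_serial = don$serial[i], acc_serial = acc$serial[j],
        donor_side = donor_side)
    }
  }
  if (length(rows)) do.call(rbind, rows) else empty_interactions()
}

#' Detect hydrogen bonds
#'
#' Both directions (ligand donor vs receptor acceptor, and vice versa) are
#' evaluated: heavy-atom donor-acceptor distance at or below
#' `hbond_dist_max` and D-H...A angle at or above `hbond_don_angle_min`.
#' Donors whose hydrogen could not be placed are evaluated distance-only and
#' flagged `unverified` (lower confidence).
#'
#' @inheritParams detect_hydrophobic
#' @return interaction data frame with donor/acceptor roles, D...A and H...A
#'   distances and the donor angle
#' @export
detect_hbonds <- function(lf, rf, atoms, cfg = default_config()) {
  rbind(hbond_pairs_one_way(lf$donors, rf$acceptors, atoms, cfg, "ligand"),
        hbond_pairs_one_way(rf$donors, lf$acceptors, atoms, cfg, "receptor"))
}

polar_atoms <- function(f) {
  nd <- nrow(f$donors); na <- nrow(f$acceptors)
  unique(rbind(
    data.frame(serial = f$donors$serial, role = rep("donor", nd),
               no_h = f$donors$no_h,
               resname = f$donors$resname, chain = f$donors$chain,
               resseq = f$donors$resseq, icode = f$donors$icode,
               stringsAsFactors = FALSE),
    data.frame(serial = f$acceptors$serial, role = rep("acceptor", na),
               no_h = rep(FALSE, na),
               resname = f$acceptors$resname, chain = f$acceptors$chain,
               resseq = f$acceptors$resseq, icode = f$acceptors$icode,
               stringsAsFactors = FALSE)))
}

#' Detect water-mediated hydrogen-bond bridges
#'
#' A ligand polar atom and a receptor polar atom each within
#' `[water_bridge_mindist, water_bridge_maxdist]` of the same water oxygen,
#' with the water-centred angle within `[omega_min, omega_max]`; one leg must
#' be donor-like and the other acceptor-like via the water.
#'
#' @inheritParams detect_hydrophobic
#' @param waters data frame of water oxygens (`serial`, residue columns)
#' @return interaction data frame (dist = ligand leg, dist2 = receptor leg,
#'   angle = water-centred angle, `water_serial` names the bridging water)
#' @export
detect_water_bridges <- function(lf, rf, waters, atoms, cfg = default_config()) {
  out <- empty_interactions()
  if (is.null(waters) || !nrow(waters)) return(out)
  lp <- polar_atoms(lf); rp <- polar_atoms(rf)
  if (!nrow(lp) || !nrow(rp)) return(out)
  rows <- list()
  for (w in seq_len(nrow(waters))) {
    wo <- coords_of(atoms, waters$serial[w])
    for (i in seq_len(nrow(lp))) {
      li <- coords_of(atoms, lp$serial[i])
      d1 <- dist3(li, wo)
      if (d1 < cfg$water_bridge_mindist || d1 > cfg$water_bridge_maxdist) next
      for (j in seq_len(nrow(rp))) {
        ri <- coords_of(atoms, rp$serial[j])
        d2 <- dist3(ri, wo)
        if (d2 < cfg$water_bridge_mindist || d2 > cfg$water_bridge_maxdist) next
        # one leg donor-like, the other acceptor-like
        if (!((lp$role[i] == "donor" && rp$role[j] == "acceptor") ||
              (lp$role[i] == "acceptor" && rp$role[j] == "donor"))) next
        om <- angle3(li, wo, ri)
        if (om < cfg$water_bridge_omega_min || om > cfg$water_bridge_omega_max) next
        rows[[length(rows) + 1]] <- interaction_row(
          "waterbridge", lp$serial[i], rp$serial[j],
          meta_of_row(lp, i), meta_of_row(rp, j),
          dist = d1, dist2 = d2, angle = om,
          donor_side = if (lp$role[i] == "donor") "ligand" else "receptor",
          water_serial = waters$serial[w])
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else out
}

#' Detect salt bridges
#'
#' Opposite-sign charged-centre pairs with centroid distance at or below
#' `saltbridge_dist_max`. Nucleic phosphate groups are eligible negative
#' partners.
#'
#' @inheritParams detect_hydrophobic
#' @return interaction data frame (`geom_label` records which side carries
#'   the positive charge)
#' @export
detect_salt_bridges <- function(lf, rf, atoms, cfg = default_config()) {
  rows <- list()
  pair_up <- function(pos, neg, pos_side) {
    for (i in seq_len(nrow(pos))) for (j in seq_len(nrow(neg))) {
      d <- dist3(c(pos$cx[i], pos$cy[i], pos$cz[i]),
                 c(neg$cx[j], neg$cy[j], neg$cz[j]))
      if (d > cfg$saltbridge_dist_max) next
      lig <- if (pos_side == "ligand") pos else neg
      rec <- if (pos_side == "ligand") neg else pos
      li <- if (pos_side == "ligand") i else j
      ri <- if (pos_side == "ligand") j else i
      rows[[length(rows) + 1]] <<- interaction_row(
        "saltbridge", sort(lig$serials[[li]]), sort(rec$serials[[ri]]),
        meta_of_row(lig, li), meta_of_row(rec, ri),
        dist = d, geom_label = paste0("positive_", pos_side))
    }
  }
  pair_up(lf$pos_centers, rf$neg_centers, "ligand")
  pair_up(rf$pos_centers, lf$neg_centers, "receptor")
  if (length(rows)) do.call(rbind, rows) else empty_interactions()
}

#' Detect pi-stacking
#'
#' Ring pairs with centroid distance at or below `pistack_dist_max`,
#' interplanar angle within `pistack_ang_dev` of 0 (parallel, label P) or of
#' 90 degrees (T-shape, label T), and lateral offset (projection of the
#' centroid vector onto each ring plane, minimum of the two) at or below
#' `pistack_offset_max`. Purine bases contribute their 5-ring, 6-ring and
#' fused composite; duplicates are reduced in refinement.
#'
#' @inheritParams detect_hydrophobic
#' @return interaction data frame (dist, interplanar angle, offset, label)
#' @export
detect_pistacking <- function(lf, rf, atoms, cfg = default_config()) {
  lr <- lf$rings; rr <- rf$rings
  rows <- list()
  for (i in seq_len(nrow(lr))) for (j in seq_len(nrow(rr))) {
    c1 <- c(lr$cx[i], lr$cy[i], lr$cz[i])
    c2 <- c(rr$cx[j], rr$cy[j], rr$cz[j])
    d <- dist3(c1, c2)
    if (d > cfg$pistack_dist_max) next
    n1 <- c(lr$nx[i], lr$ny[i], lr$nz[i])
    n2 <- c(rr$nx[j], rr$ny[j], rr$nz[j])
    ang <- plane_angle(n1, n2)
    label <- if (ang <= cfg$pistack_ang_dev) "P"
             else if (ang >= 90 - cfg$pistack_ang_dev) "T"
             else NA_character_
    if (is.na(label)) next
    off <- min(plane_offset(c2, c1, n1), plane_offset(c1, c2, n2))
    if (off > cfg$pistack_offset_max) next
    rows[[length(rows) + 1]] <- interaction_row(
      "pistacking", sort(lr$serials[[i]]), sort(rr$serials[[j]]),
      meta_of_row(lr, i), meta_of_row(rr, j),
      dist = d, angle = ang, offset = off, geom_label = label)
  }
  if (length(rows)) do.call(rbind, rows) else empty_interactions()
}

#' Detect pi-cation interactions
#'
#' (Ring, positive centre) pairs with centroid-charge distance at or below
#' `pication_dist_max`. For guanidinium cations an approximately face-on
#' approach is additionally required: angle between the ring normal and the
#' centroid-to-cation vector at most 30 degrees. Nucleic base rings are
#' eligible pi partners.
#'
#' @inheritParams detect_hydrophobic
#' @return interaction data frame
#' @export
detect_pication <- function(lf, rf, atoms, cfg = default_config()) {
  rows <- list()
  pair_up <- function(rings, cats, ring_side) {
    for (i in seq_len(nrow(rings))) for (j in seq_len(nrow(cats))) {
      ctr <- c(rings$cx[i], rings$cy[i], rings$cz[i])
      cat_c <- c(cats$cx[j], cats$cy[j], cats$cz[j])
      d <- dist3(ctr, cat_c)
      if (d > cfg$pication_dist_max) next
      nrm <- c(rings$nx[i], rings$ny[i], rings$nz[i])
      a <- vec_angle(nrm, cat_c - ctr)
      a <- min(a, 180 - a)
      if (cats$kind[j] == "guanidinium" && a > 30) next
      lig <- if (ring_side == "ligand") rings else cats
      rec <- if (ring_side == "ligand") cats else rings
      li <- if (ring_side == "ligand") i else j
      ri <- if (ring_side == "ligand") j else i
      rows[[length(rows) + 1]] <<- interaction_row(
        "pication", sort(lig$serials[[li]]), sort(rec$serials[[ri]]),
        meta_of_row(lig, li), meta_of_row(rec, ri),
        dist = d, angle = a,
        geom_label = paste0("ring_", ring_side))
    }
  }
  pair_up(lf$rings, rf$pos_centers, "ligand")
  pair_up(rf$rings, lf$pos_centers, "receptor")
  if (length(rows)) do.call(rbind, rows) else empty_interactions()
}

#' Detect halogen bonds
#'
#' Ligand carbon-halogen donors against receptor O/N/S acceptors with a
#' known attached heavy atom: X...A distance at or below `halogen_dist_max`,
#' donor angle C-X...A within `halogen_don_angle +/- halogen_don_angle_dev`,
#' acceptor angle Y-A...X within `halogen_acc_angle +/- halogen_acc_angle_dev`.
#'
#' @inheritParams detect_hydrophobic
#' @return interaction data frame (angle = donor angle, angle2 = acceptor
#'   angle)
#' @export
detect_halogen_bonds <- function(lf, rf, atoms, cfg = default_config()) {
  rows <- list()
  pair_up <- function(dons, accs, donor_side) {
    for (i in seq_len(nrow(dons))) for (j in seq_len(nrow(accs))) {
      if (is.na(accs$y_serial[j])) next
      x <- coords_of(atoms, dons$x_serial[i])
      cc <- coords_of(atoms, dons$c_serial[i])
      a <- coords_of(atoms, accs$serial[j])
      y <- coords_of(atoms, accs$y_serial[j])
      d <- dist3(x, a)
      if (d > cfg$halogen_dist_max) next
      don_ang <- angle3(cc, x, a)
      if (abs(don_ang - cfg$halogen_don_angle) > cfg$halogen_don_angle_dev) next
      acc_ang <- angle3(y, a, x)
      if (abs(acc_ang - cfg$halogen_acc_angle) > cfg$halogen_acc_angle_dev) next
      lm <- if (donor_side == "ligand") meta_of_row(dons, i) else meta_of_row(accs, j)
      rm <- if (donor_side == "ligand") meta_of_row(accs, j) else meta_of_row(dons, i)
      lser <- if (donor_side == "ligand") dons$x_serial[i] else accs$serial[j]
      rser <- if (donor_side == "ligand") accs$serial[j] else dons$x_serial[i]
      rows[[length(rows) + 1]] <<- interaction_row(
        "halogen", lser, rser, lm, rm,
        dist = d, angle = don_ang, angle2 = acc_ang,
        don_serial = dons$x_serial[i], acc_serial = accs$serial[j],
        donor_side = donor_side)
    }
  }
  pair_up(lf$halogen_donors, rf$acceptors, "ligand")
  pair_up(rf$halogen_donors, lf$acceptors, "receptor")
  if (length(rows)) do.call(rbind, rows) else empty_interactions()
}

METAL_GEOMETRY_TEMPLATES <- list(
  "2" = list(linear = c(180)),
  "3" = list(trigonal_planar = c(120, 120, 120)),
  "4" = list(tetrahedral = rep(109.47, 6),
             square_planar = c(rep(90, 4), 180, 180)),
  "5" = list(trigonal_bipyramidal = c(rep(90, 6), rep(120, 3), 180),
             square_pyramidal = c(rep(90, 8), 180, 180)),
  "6" = list(octahedral = c(rep(90, 12), rep(180, 3)))
)

metal_geometry_label <- function(metal_xyz, target_xyz) {
  n <- nrow(target_xyz)
  if (n < 2) return(list(label = "other/underdetermined", rmsd = NA_real_))
  tmpl <- METAL_GEOMETRY_TEMPLATES[[as.character(n)]]
  if (is.null(tmpl)) return(list(label = "other/underdetermined", rmsd = NA_real_))
  angs <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    angs <- c(angs, angle3(target_xyz[i, ], metal_xyz, target_xyz[j, ]))
  angs <- sort(angs)
  best <- NULL
  for (nm in names(tmpl)) {
    r <- sqrt(mean((angs - sort(tmpl[[nm]]))^2))
    if (is.null(best) || r < best$rmsd) best <- list(label = nm, rmsd = r)
  }
  best
}

#' Detect metal coordination complexes
#'
#' Metal atoms from either side (ligand ions or in-site metals) against
#' coordination-capable targets: O, N and S atoms of the opposite analysis
#' content plus water oxygens, within `metal_dist_max`. The full coordination
#' sphere is grouped per metal and an idealised geometry label (linear,
#' trigonal planar, tetrahedral, square planar, trigonal bipyramidal,
#' square pyramidal, octahedral) is assigned by best-fit angular RMSD over
#' canonical templates; a single-partner sphere is labelled
#' "other/underdetermined".
#'
#' @inheritParams detect_hydrophobic
#' @param waters data frame of water oxygens
#' @return one interaction row per coordination contact, carrying the
#'   geometry label and the number of coordinating partners of its metal
#' @export
detect_metal_complexes <- function(lf, rf, waters, atoms, cfg = default_config()) {
  ml <- lf$metals; ml$side <- rep("ligand", nrow(ml))
  mr <- rf$metals; mr$side <- rep("receptor", nrow(mr))
  metals <- rbind(ml, mr)
  if (!nrow(metals)) return(empty_interactions())
  target_pool <- function(f, side) {
    # all O/N/S atoms carried by this side, via its polar features
    ser <- unique(c(f$donors$serial, f$acceptors$serial,
                    unlist(f$neg_centers$serials)))
    at <- atoms[match(ser, atoms$serial), , drop = FALSE]
    at <- at[at$element %in% c("O", "N", "S"), , drop = FALSE]
    if (!nrow(at)) return(NULL)
    data.frame(serial = at$serial, resname = at$resname, chain = at$chain,
               resseq = at$resseq, icode = at$icode, side = side,
               stringsAsFactors = FALSE)
  }
  targets <- rbind(target_pool(lf, "ligand"), target_pool(rf, "receptor"))
  if (!is.null(waters) && nrow(waters))
    targets <- rbind(targets,
                     data.frame(serial = waters$serial,
                                resname = waters$resname, chain = waters$chain,
                                resseq = waters$resseq, icode = waters$icode,
                                side = "water", stringsAsFactors = FALSE))
  if (is.null(targets) || !nrow(targets)) return(empty_interactions())
  targets <- targets[!duplicated(targets$serial), , drop = FALSE]
  rows <- list()
  for (m in seq_len(nrow(metals))) {
    mxyz <- coords_of(atoms, metals$serial[m])
    dd <- vapply(targets$serial, function(s) dist3(mxyz, coords_of(atoms, s)),
                 numeric(1))
    hit <- which(dd <= cfg$metal_dist_max & targets$serial != metals$serial[m])
    if (!length(hit)) next
    txyz <- t(vapply(targets$serial[hit], coords_of, numeric(3), atoms = atoms))
    geo <- metal_geometry_label(mxyz, txyz)
    for (hidx in seq_along(hit)) {
      j <- hit[hidx]
      lig_side_metal <- metals$side[m] == "ligand"
      mmeta <- data.frame(resname = metals$resname[m], chain = metals$chain[m],
                          resseq = metals$resseq[m], icode = metals$icode[m],
                          stringsAsFactors = FALSE)
      tmeta <- data.frame(resname = targets$resname[j], chain = targets$chain[j],
                          resseq = targets$resseq[j], icode = targets$icode[j],
                          stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- interaction_row(
        "metal",
        lig_serials = if (lig_side_metal) metals$serial[m] else targets$serial[j],
        rec_serials = if (lig_side_metal) targets$serial[j] else metals$serial[m],
        lig_meta = if (lig_side_metal) mmeta else tmeta,
        rec_meta = if (lig_side_metal) tmeta else mmeta,
        dist = dd[j], geom_label = geo$label, coord_num = length(hit),
        don_serial = metals$serial[m], acc_serial = targets$serial[j])
    }
  }
  if (length(rows)) do.call(rbind, rows) else empty_interactions()
}

serial_set <- function(x) as.integer(unlist(strsplit(x, ",", fixed = TRUE)))

#' Refine raw interactions
#'
#' Deterministic refinement applied after detection:
#' (a) hydrophobic clustering (idempotent re-application of the reduction in
#' [detect_hydrophobic()]); (b) a water bridge is suppressed when the same
#' ligand-atom/receptor-atom pair also forms a direct hydrogen bond; (c) a
#' salt bridge subsumes the individual hydrogen bonds between member atoms
#' of its two charged groups; (d) duplicate pi-stacks (and pi-cation
#' contacts) arising from the purine multi-ring representation keep only the
#' best-offset (respectively closest) record per ring-group pair; (e) a pair
#' reported as pi-cation is not additionally reported as a salt bridge for
#' the same centroids; (f) a donor atom donates at most one hydrogen bond:
#' among its candidates the largest donor angle wins (ties to the smaller
#' distance).
#'
#' @param inter raw interaction data frame (all detectors row-bound)
#' @param lf,rf the feature sets used at detection time (for group lookup)
#' @return refined interaction data frame in deterministic order
#' @export
refine_interactions <- function(inter, lf = NULL, rf = NULL) {
  if (!nrow(inter)) return(inter)
  keep <- rep(TRUE, nrow(inter))

  is_type <- function(t) inter$type == t

  # (a) hydrophobic reduction (idempotent)
  if (any(is_type("hydrophobic"))) {
    red <- reduce_hydrophobic(inter[is_type("hydrophobic"), , drop = FALSE])
    sig <- function(df) paste(df$lig_serials, df$rec_serials)
    keep[is_type("hydrophobic")] <-
      sig(inter[is_type("hydrophobic"), ]) %in% sig(red)
  }

  # (b) direct H-bond beats water bridge for the same atom pair
  hb <- inter[is_type("hbond") & keep, , drop = FALSE]
  if (nrow(hb)) {
    hb_pairs <- paste(hb$lig_serials, hb$rec_serials)
    wb_idx <- which(is_type("waterbridge"))
    for (i in wb_idx) {
      if (paste(inter$lig_serials[i], inter$rec_serials[i]) %in% hb_pairs)
        keep[i] <- FALSE
    }
  }

  # (c) salt bridge subsumes H-bonds between members of its groups
  sb_idx <- which(is_type("saltbridge") & keep)
  if (length(sb_idx)) {
    hb_idx <- which(is_type("hbond"))
    for (si in sb_idx) {
      lig_grp <- serial_set(inter$lig_serials[si])
      rec_grp <- serial_set(inter$rec_serials[si])
      for (hi in hb_idx) {
        if (!keep[hi]) next
        if (serial_set(inter$lig_serials[hi]) %in% lig_grp &&
            serial_set(inter$rec_serials[hi]) %in% rec_grp)
          keep[hi] <- FALSE
      }
    }
  }

  # (f) one hydrogen bond per donor atom: keep the best-angle candidate
  # (largest D-H...A angle; ties to smaller distance, then serial order);
  # distance-only (unverified) candidates keep the closest acceptor
  hb_idx <- which(is_type("hbond") & keep)
  if (length(hb_idx) > 1) {
    don <- inter$don_serial[hb_idx]
    for (dser in unique(don)) {
      members <- hb_idx[don == dser]
      if (length(members) < 2) next
      ang <- inter$angle[members]
      ang[is.na(ang)] <- -1   # unverified sort after any measured angle
      best <- members[order(-ang, inter$dist[members],
                            inter$acc_serial[members])][1]
      keep[setdiff(members, best)] <- FALSE
    }
  }

  # (d) purine / fused multi-ring duplicates: one record per ring-group pair
  dedupe_groups <- function(idx, better) {
    if (length(idx) < 2) return()
    grp_of <- function(serials_chr, f1, f2) {
      ss <- serial_set(serials_chr)
      for (f in list(f1, f2)) {
        if (is.null(f) || !nrow(f$rings)) next
        for (r in seq_len(nrow(f$rings)))
          if (all(ss %in% f$rings$serials[[r]]) ||
              all(f$rings$serials[[r]] %in% ss))
            return(f$rings$group[r])
      }
      serials_chr
    }
    gl <- vapply(inter$lig_serials[idx], grp_of, character(1), f1 = lf, f2 = NULL)
    gr <- vapply(inter$rec_serials[idx], grp_of, character(1), f1 = rf, f2 = NULL)
    key <- paste(gl, gr)
    for (k in unique(key)) {
      members <- idx[key == k]
      if (length(members) < 2) next
      best <- members[order(better[match(members, idx)],
                            inter$dist[members])][1]
      keep[setdiff(members, best)] <<- FALSE
    }
  }
  ps_idx <- which(is_type("pistacking") & keep)
  dedupe_groups(ps_idx, inter$offset[ps_idx])
  pc_idx <- which(is_type("pication") & keep)
  dedupe_groups(pc_idx, inter$dist[pc_idx])

  # (e) pi-cation wins over salt bridge for the same centroids
  pc_idx <- which(is_type("pication") & keep)
  sb_idx <- which(is_type("saltbridge") & keep)
  for (si in sb_idx) {
    sl <- serial_set(inter$lig_serials[si]); sr <- serial_set(inter$rec_serials[si])
    for (pi in pc_idx) {
      pl <- serial_set(inter$lig_serials[pi]); pr <- serial_set(inter$rec_serials[pi])
      if ((all(sl %in% pl) || all(pl %in% sl)) &&
          (length(intersect(sr, pr)) > 0 || all(sr %in% pr))) {
        keep[si] <- FALSE
        break
      }
      if ((all(sr %in% pr) || all(pr %in% sr)) &&
          length(intersect(sl, pl)) > 0) {
        keep[si] <- FALSE
        break
      }
    }
  }

  out <- inter[keep, , drop = FALSE]
  sort_interactions(out)
}

sort_interactions <- function(inter) {
  if (!nrow(inter)) return(inter)
  ord <- order(match(inter$type, INTERACTION_TYPES),
               inter$rec_chain, inter$rec_resseq, inter$rec_icode,
               inter$dist, inter$rec_serials, inter$lig_serials)
  inter <- inter[ord, , drop = FALSE]
  rownames(inter) <- NULL
  inter
}

#' Run every detector against a prepared binding site
#'
#' @param site an `nci_site` (receptor scope already applied)
#' @param atoms atom table of the selected model
#' @param waters data frame of water oxygens near the ligand
#' @param cfg an `nci_config`
#' @param mode an [analysis_mode()]
#' @param conect CONECT edge list of the structure
#' @return refined interaction data frame
#' @export
detect_interactions <- function(site, atoms, waters = NULL,
                                cfg = default_config(),
                                mode = analysis_mode(), conect = NULL) {
  lf <- perceive_features(site$ligand$atoms, conect, mode)
  rf <- perceive_features(site$receptor_atoms, conect, mode)
  raw <- rbind(
    detect_hydrophobic(lf, rf, atoms, cfg),
    detect_hbonds(lf, rf, atoms, cfg),
    detect_water_bridges(lf, rf, waters, atoms, cfg),
    detect_salt_bridges(lf, rf, atoms, cfg),
    detect_pistacking(lf, rf, atoms, cfg),
    detect_pication(lf, rf, atoms, cfg),
    detect_halogen_bonds(lf, rf, atoms, cfg),
    detect_metal_complexes(lf, rf, waters, atoms, cfg)
  )
  refine_interactions(raw, lf, rf)
}
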