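# Independent brute-force oracles and random micro-geometry builders.
# The oracles re-state each geometric rule with plain nested loops and their
# own vector arithmetic; they never call the package's detector internals.

o_dist <- function(a, b) sqrt(sum((a - b)^2))

o_angle <- function(a, v, b) {
  u1 <- a - v; u2 <- b - v
  acos(max(-1, min(1, sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))))) * 180 / pi
}

o_plane <- function(pts) {
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  n <- eigen(crossprod(x))$vectors[, 3]
  list(centroid = ctr, normal = n / sqrt(sum(n^2)))
}

o_offset <- function(p, ctr, n) {
  d <- p - ctr
  sqrt(max(0, sum(d^2) - sum(d * n)^2))
}

# atom table builder for synthesized feature sets
mk_atom_table <- function(coords, serial_start = 1L, element = "C") {
  n <- nrow(coords)
  data.frame(serial = serial_start + seq_len(n) - 1L,
             name = paste0("X", seq_len(n)), altloc = "",
             resname = "UNL", chain = "L", resseq = 1L, icode = "",
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             occ = 1, element = rep(element, length.out = n),
             hetero = TRUE, model = 1L, stringsAsFactors = FALSE)
}

meta_df <- function(n, resname = "UNL", chain = "L", resseq = 1L) {
  data.frame(resname = rep(resname, n), chain = rep(chain, n),
             resseq = rep(as.integer(resseq), n), icode = rep("", n),
             stringsAsFactors = FALSE)
}

# feature-frame builders matching the perception output layout
ff_hydrophobic <- function(serials, resname = "UNL", chain = "L", resseq = 1L) {
  cbind(data.frame(serial = serials), meta_df(length(serials), resname,
                                              chain, resseq))
}

ff_donors <- function(serials, h_serials, no_h = FALSE,
                      resname = "UNL", chain = "L", resseq = 1L) {
  cbind(data.frame(serial = serials,
                   no_h = rep(no_h, length.out = length(serials))),
        meta_df(length(serials), resname, chain, resseq),
        data.frame(h_serials = I(h_serials)))
}

ff_acceptors <- function(serials, y_serials = NA,
                         resname = "UNL", chain = "L", resseq = 1L) {
  cbind(data.frame(serial = serials,
                   y_serial = rep(y_serials, length.out = length(serials))),
        meta_df(length(serials), resname, chain, resseq))
}

ff_centers <- function(centroids, kind, serials_list,
                       resname = "UNL", chain = "L", resseq = 1L) {
  centroids <- matrix(centroids, ncol = 3)
  cbind(data.frame(cx = centroids[, 1], cy = centroids[, 2],
                   cz = centroids[, 3],
                   kind = rep(kind, length.out = nrow(centroids))),
        meta_df(nrow(centroids), resname, chain, resseq),
        data.frame(serials = I(serials_list)))
}

ff_rings <- function(centroids, normals, serials_list, groups = NULL,
                     resname = "UNL", chain = "L", resseq = 1L) {
  centroids <- matrix(centroids, ncol = 3)
  normals <- matrix(normals, ncol = 3)
  n <- nrow(centroids)
  if (is.null(groups)) groups <- paste0("g", seq_len(n))
  cbind(data.frame(cx = centroids[, 1], cy = centroids[, 2],
                   cz = centroids[, 3],
                   nx = normals[, 1], ny = normals[, 2], nz = normals[, 3],
                   rmsd = rep(0, n), label = rep("6-ring", n),
                   group = groups),
        meta_df(n, resname, chain, resseq),
        data.frame(serials = I(serials_list)))
}

features_from <- function(...) {
  f <- nciprofiler:::empty_features()
  parts <- list(...)
  for (k in names(parts)) f[[k]] <- parts[[k]]
  f
}

# random features for the oracle-equivalence property; one seeded draw per
# repetition, geometry confined to a 12 A box
random_case <- function(seed, kind) {
  set.seed(seed)
  rnd <- function(n) matrix(stats::runif(n * 3, 0, 12), ncol = 3)
  if (kind == "hydrophobic") {
    nl <- sample(2:8, 1); nr <- sample(2:8, 1)
    lc <- rnd(nl); rc <- rnd(nr)
    atoms <- rbind(mk_atom_table(lc), mk_atom_table(rc, 100L))
    # receptor carbons spread over up to 3 residues so stage-1 reduction
    # has structure
    rres <- sample(1:3, nr, replace = TRUE)
    lf <- features_from(hydrophobics = ff_hydrophobic(seq_len(nl)))
    rfh <- ff_hydrophobic(100:(99 + nr), resname = "ALA", chain = "A",
                          resseq = 1L)
    rfh$resseq <- rres
    rf <- features_from(hydrophobics = rfh)
    return(list(lf = lf, rf = rf, atoms = atoms))
  }
  if (kind == "hbond") {
    nd <- sample(1:4, 1); na <- sample(1:4, 1)
    dc <- rnd(nd); hc <- dc + matrix(stats::rnorm(nd * 3, 0, 0.6), ncol = 3)
    hc <- dc + (hc - dc) / sqrt(rowSums((hc - dc)^2)) * 1.01
    ac <- rnd(na)
    atoms <- rbind(mk_atom_table(dc, 1L, "N"),
                   mk_atom_table(hc, 50L, "H"),
                   mk_atom_table(ac, 100L, "O"))
    lf <- features_from(donors = ff_donors(seq_len(nd),
                                           as.list(50:(49 + nd))))
    rf <- features_from(acceptors = ff_acceptors(100:(99 + na),
                                                 resname = "ALA",
                                                 chain = "A"))
    return(list(lf = lf, rf = rf, atoms = atoms))
  }
  if (kind == "waterbridge") {
    np <- sample(1:3, 1); nq <- sample(1:3, 1); nw <- sample(1:3, 1)
    lc <- rnd(np); rc <- rnd(nq); wc <- rnd(nw)
    atoms <- rbind(mk_atom_table(lc, 1L, "O"), mk_atom_table(rc, 100L, "O"),
                   mk_atom_table(wc, 200L, "O"))
    lrole <- sample(c("donor", "acceptor"), np, replace = TRUE)
    rrole <- sample(c("donor", "acceptor"), nq, replace = TRUE)
    lf <- features_from(
      donors = ff_donors(which(lrole == "donor"),
                         lapply(seq_len(sum(lrole == "donor")),
                                function(i) integer(0))),
      acceptors = ff_acceptors(which(lrole == "acceptor")))
    rf <- features_from(
      donors = ff_donors(99L + which(rrole == "donor"),
                         lapply(seq_len(sum(rrole == "donor")),
                                function(i) integer(0)),
                         resname = "SER", chain = "A"),
      acceptors = ff_acceptors(99L + which(rrole == "acceptor"),
                               resname = "SER", chain = "A"))
    waters <- data.frame(serial = 200:(199 + nw), resname = "HOH",
                         chain = "W", resseq = seq_len(nw), icode = "",
                         stringsAsFactors = FALSE)
    return(list(lf = lf, rf = rf, atoms = atoms, waters = waters,
                lrole = lrole, rrole = rrole))
  }
  if (kind == "saltbridge") {
    np <- sample(1:3, 1); nn <- sample(1:3, 1)
    pc <- rnd(np); nc <- rnd(nn)
    lf <- features_from(pos_centers = ff_centers(pc, "amine",
                                                 as.list(seq_len(np))))
    rf <- features_from(neg_centers = ff_centers(nc, "carboxylate",
                                                 as.list(100:(99 + nn)),
                                                 resname = "ASP", chain = "A"))
    return(list(lf = lf, rf = rf, atoms = mk_atom_table(rnd(1))))
  }
  if (kind %in% c("pistacking", "pication")) {
    n1 <- sample(1:3, 1); n2 <- sample(1:3, 1)
    c1 <- rnd(n1); c2 <- rnd(n2)
    nrm <- function(n) {
      m <- matrix(stats::rnorm(n * 3), ncol = 3)
      m / sqrt(rowSums(m^2))
    }
    lf <- features_from(rings = ff_rings(c1, nrm(n1),
                                         as.list(seq_len(n1))))
    if (kind == "pistacking") {
      rf <- features_from(rings = ff_rings(c2, nrm(n2),
                                           as.list(100:(99 + n2)),
                                           resname = "PHE", chain = "A"))
    } else {
      kinds <- sample(c("guanidinium", "amine"), n2, replace = TRUE)
      rf <- features_from(pos_centers = ff_centers(c2, kinds,
                                                   as.list(100:(99 + n2)),
                                                   resname = "ARG",
                                                   chain = "A"))
    }
    return(list(lf = lf, rf = rf, atoms = mk_atom_table(rnd(1))))
  }
  if (kind == "halogen") {
    nx <- sample(1:3, 1); na <- sample(1:3, 1)
    xc <- rnd(nx); cc <- xc + 1.77 * nrm0(nx)
    ac <- rnd(na); yc <- ac + 1.4 * nrm0(na)
    atoms <- rbind(mk_atom_table(xc, 1L, "Cl"), mk_atom_table(cc, 50L, "C"),
                   mk_atom_table(ac, 100L, "O"), mk_atom_table(yc, 150L, "C"))
    lf <- features_from(halogen_donors = cbind(
      data.frame(x_serial = seq_len(nx), c_serial = 50:(49 + nx)),
      meta_df(nx)))
    rf <- features_from(acceptors = ff_acceptors(100:(99 + na),
                                                 150:(149 + na),
                                                 resname = "ALA", chain = "A"))
    return(list(lf = lf, rf = rf, atoms = atoms))
  }
  if (kind == "metal") {
    nt <- sample(2:7, 1)
    mc <- matrix(c(6, 6, 6), 1)
    tc <- mc[rep(1, nt), , drop = FALSE] +
      matrix(stats::runif(nt * 3, -3.5, 3.5), ncol = 3)
    atoms <- rbind(mk_atom_table(mc, 1L, "Mg"),
                   mk_atom_table(tc, 100L, "O"))
    lf <- features_from(metals = cbind(
      data.frame(serial = 1L, element = "Mg"),
      meta_df(1, resname = "MG", chain = "L")))
    rf <- features_from(acceptors = ff_acceptors(100:(99 + nt),
                                                 resname = "ASP",
                                                 chain = "A"))
    return(list(lf = lf, rf = rf, atoms = atoms))
  }
  stop("unknown kind")
}

nrm0 <- function(n) {
  m <- matrix(stats::rnorm(n * 3), ncol = 3)
  m / sqrt(rowSums(m^2))
}

xyz_of <- function(atoms, serial) {
  as.numeric(atoms[match(serial, atoms$serial), c("x", "y", "z")])
}

# ---- per-detector oracles (raw rule, inclusive bounds) ----

oracle_hydrophobic_pairs <- function(lf, rf, atoms, cfg) {
  out <- list()
  for (i in seq_len(nrow(lf$hydrophobics))) {
    for (j in seq_len(nrow(rf$hydrophobics))) {
      d <- o_dist(xyz_of(atoms, lf$hydrophobics$serial[i]),
                  xyz_of(atoms, rf$hydrophobics$serial[j]))
      if (d <= cfg$hydroph_dist_max)
        out[[length(out) + 1]] <- list(l = lf$hydrophobics$serial[i],
                                       r = rf$hydrophobics$serial[j],
                                       rres = rf$hydrophobics$resseq[j],
                                       d = d)
    }
  }
  out
}

# independent restatement of the two-stage hydrophobic reduction
oracle_hydrophobic <- function(lf, rf, atoms, cfg) {
  pairs <- oracle_hydrophobic_pairs(lf, rf, atoms, cfg)
  if (!length(pairs)) return(pairs)
  # stage 1: min per (ligand atom, receptor residue)
  key <- vapply(pairs, function(p) paste(p$l, p$rres), character(1))
  kept <- list()
  for (k in unique(key)) {
    grp <- pairs[key == k]
    ds <- vapply(grp, `[[`, numeric(1), "d")
    rs <- vapply(grp, `[[`, numeric(1), "r")
    ls <- vapply(grp, `[[`, numeric(1), "l")
    kept[[length(kept) + 1]] <- grp[[order(ds, rs, ls)[1]]]
  }
  # stage 2: fully connected components collapse to one contact
  ls <- vapply(kept, `[[`, numeric(1), "l")
  rs <- vapply(kept, `[[`, numeric(1), "r")
  ds <- vapply(kept, `[[`, numeric(1), "d")
  # connected components via repeated expansion
  comp <- seq_along(kept)
  repeat {
    changed <- FALSE
    for (i in seq_along(kept)) for (j in seq_along(kept)) {
      if (comp[i] != comp[j] && (ls[i] == ls[j] || rs[i] == rs[j])) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  final <- list()
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    lmem <- unique(ls[idx]); rmem <- unique(rs[idx])
    if (length(idx) == length(lmem) * length(rmem) && length(idx) > 1) {
      best <- idx[order(ds[idx], rs[idx], ls[idx])[1]]
      final[[length(final) + 1]] <- kept[[best]]
    } else {
      final <- c(final, kept[idx])
    }
  }
  final
}

oracle_hbond <- function(lf, rf, atoms, cfg) {
  out <- list()
  eval_dir <- function(don, acc, side) {
    for (i in seq_len(nrow(don))) for (j in seq_len(nrow(acc))) {
      if (don$serial[i] == acc$serial[j]) next
      d <- xyz_of(atoms, don$serial[i])
      a <- xyz_of(atoms, acc$serial[j])
      dd <- o_dist(d, a)
      if (dd > cfg$hbond_dist_max) next
      hs <- don$h_serials[[i]]
      if (don$no_h[i] || !length(hs)) {
        out[[length(out) + 1]] <<- list(don = don$serial[i],
                                        acc = acc$serial[j], side = side,
                                        d = dd, ang = NA, unverified = TRUE)
        next
      }
      angs <- vapply(hs, function(h) o_angle(d, xyz_of(atoms, h), a),
                     numeric(1))
      if (max(angs) >= cfg$hbond_don_angle_min)
        out[[length(out) + 1]] <<- list(don = don$serial[i],
                                        acc = acc$serial[j], side = side,
                                        d = dd, ang = max(angs),
                                        unverified = FALSE)
    }
  }
  eval_dir(lf$donors, rf$acceptors, "ligand")
  eval_dir(rf$donors, lf$acceptors, "receptor")
  out
}

oracle_waterbridge <- function(lf, rf, waters, atoms, cfg, lrole, rrole) {
  out <- list()
  lser <- c(lf$donors$serial, lf$acceptors$serial)
  lrl <- c(rep("donor", nrow(lf$donors)), rep("acceptor", nrow(lf$acceptors)))
  rser <- c(rf$donors$serial, rf$acceptors$serial)
  rrl <- c(rep("donor", nrow(rf$donors)), rep("acceptor", nrow(rf$acceptors)))
  for (w in waters$serial) for (i in seq_along(lser)) for (j in seq_along(rser)) {
    if (lrl[i] == rrl[j]) next
    wo <- xyz_of(atoms, w)
    d1 <- o_dist(xyz_of(atoms, lser[i]), wo)
    d2 <- o_dist(xyz_of(atoms, rser[j]), wo)
    if (d1 < cfg$water_bridge_mindist || d1 > cfg$water_bridge_maxdist) next
    if (d2 < cfg$water_bridge_mindist || d2 > cfg$water_bridge_maxdist) next
    om <- o_angle(xyz_of(atoms, lser[i]), wo, xyz_of(atoms, rser[j]))
    if (om < cfg$water_bridge_omega_min || om > cfg$water_bridge_omega_max) next
    out[[length(out) + 1]] <- list(l = lser[i], r = rser[j], w = w)
  }
  out
}

oracle_saltbridge <- function(lf, rf, cfg) {
  out <- list()
  eval_dir <- function(pos, neg) {
    for (i in seq_len(nrow(pos))) for (j in seq_len(nrow(neg))) {
      d <- o_dist(c(pos$cx[i], pos$cy[i], pos$cz[i]),
                  c(neg$cx[j], neg$cy[j], neg$cz[j]))
      if (d <= cfg$saltbridge_dist_max)
        out[[length(out) + 1]] <<- list(p = paste(sort(pos$serials[[i]]),
                                                  collapse = ","),
                                        n = paste(sort(neg$serials[[j]]),
                                                  collapse = ","), d = d)
    }
  }
  eval_dir(lf$pos_centers, rf$neg_centers)
  eval_dir(rf$pos_centers, lf$neg_centers)
  out
}

oracle_pistacking <- function(lf, rf, cfg) {
  out <- list()
  for (i in seq_len(nrow(lf$rings))) for (j in seq_len(nrow(rf$rings))) {
    c1 <- c(lf$rings$cx[i], lf$rings$cy[i], lf$rings$cz[i])
    c2 <- c(rf$rings$cx[j], rf$rings$cy[j], rf$rings$cz[j])
    if (o_dist(c1, c2) > cfg$pistack_dist_max) next
    n1 <- c(lf$rings$nx[i], lf$rings$ny[i], lf$rings$nz[i])
    n2 <- c(rf$rings$nx[j], rf$rings$ny[j], rf$rings$nz[j])
    a <- acos(min(1, abs(sum(n1 * n2)))) * 180 / pi
    lab <- if (a <= cfg$pistack_ang_dev) "P"
           else if (a >= 90 - cfg$pistack_ang_dev) "T" else NA
    if (is.na(lab)) next
    off <- min(o_offset(c2, c1, n1), o_offset(c1, c2, n2))
    if (off > cfg$pistack_offset_max) next
    out[[length(out) + 1]] <- list(i = i, j = j, label = lab)
  }
  out
}

oracle_pication <- function(lf, rf, cfg) {
  out <- list()
  eval_dir <- function(rings, cats) {
    for (i in seq_len(nrow(rings))) for (j in seq_len(nrow(cats))) {
      ctr <- c(rings$cx[i], rings$cy[i], rings$cz[i])
      cat_c <- c(cats$cx[j], cats$cy[j], cats$cz[j])
      d <- o_dist(ctr, cat_c)
      if (d > cfg$pication_dist_max) next
      nrm <- c(rings$nx[i], rings$ny[i], rings$nz[i])
      v <- cat_c - ctr
      a <- acos(min(1, abs(sum(nrm * v)) / sqrt(sum(v^2)))) * 180 / pi
      if (cats$kind[j] == "guanidinium" && a > 30) next
      out[[length(out) + 1]] <<- list(ring = paste(sort(rings$serials[[i]]),
                                                   collapse = ","),
                                      cat = paste(sort(cats$serials[[j]]),
                                                  collapse = ","))
    }
  }
  eval_dir(lf$rings, rf$pos_centers)
  eval_dir(rf$rings, lf$pos_centers)
  out
}

oracle_halogen <- function(lf, rf, atoms, cfg) {
  out <- list()
  for (i in seq_len(nrow(lf$halogen_donors))) {
    for (j in seq_len(nrow(rf$acceptors))) {
      if (is.na(rf$acceptors$y_serial[j])) next
      x <- xyz_of(atoms, lf$halogen_donors$x_serial[i])
      cc <- xyz_of(atoms, lf$halogen_donors$c_serial[i])
      a <- xyz_of(atoms, rf$acceptors$serial[j])
      y <- xyz_of(atoms, rf$acceptors$y_serial[j])
      if (o_dist(x, a) > cfg$halogen_dist_max) next
      if (abs(o_angle(cc, x, a) - cfg$halogen_don_angle) >
          cfg$halogen_don_angle_dev) next
      if (abs(o_angle(y, a, x) - cfg$halogen_acc_angle) >
          cfg$halogen_acc_angle_dev) next
      out[[length(out) + 1]] <- list(x = lf$halogen_donors$x_serial[i],
                                     a = rf$acceptors$serial[j])
    }
  }
  out
}

oracle_metal <- function(lf, rf, atoms, cfg) {
  out <- list()
  metals <- rbind(lf$metals, rf$metals)
  targets <- unique(c(lf$donors$serial, lf$acceptors$serial,
                      rf$donors$serial, rf$acceptors$serial))
  for (m in metals$serial) for (t in targets) {
    if (m == t) next
    at <- atoms[match(t, atoms$serial), ]
    if (!(at$element %in% c("O", "N", "S"))) next
    if (o_dist(xyz_of(atoms, m), xyz_of(atoms, t)) <= cfg$metal_dist_max)
      out[[length(out) + 1]] <- list(m = m, t = t)
  }
  out
}
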