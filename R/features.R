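#' @title Functional characterisation
#'
#' @description
#' Perceives the chemical features the geometric rules consume: hydrogen-bond
#' donors and acceptors, charged centres, aromatic rings, hydrophobic atoms,
#' halogen-bond donors, metals and water oxygens.
#'
#' Standard amino-acid and nucleotide residues are characterised from
#' name-based templates shipped as a plain-text table
#' (`inst/extdata/residue_templates.tsv`); arbitrary hetero ligands are
#' characterised generically from element, valence and bond-graph rules.
#' Protonation states assume pH 7: Asp/Glu deprotonated, Arg/Lys protonated,
#' His is a donor and an acceptor and counts as cationic only when both ring
#' nitrogens carry hydrogens.
#'
#' @name functional-characterisation
NULL

.nci_cache <- new.env(parent = emptyenv())

RING_PLANARITY_RMSD_MAX <- 0.25

load_templates <- function() {
  if (!is.null(.nci_cache$templates)) return(.nci_cache$templates)
  path <- system.file("extdata", "residue_templates.tsv", package = "nciprofiler")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "residue_templates.tsv")
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           col.names = c("residue", "atom", "feature", "arg"),
                           fill = TRUE, stringsAsFactors = FALSE, quote = "")
  tab$arg <- suppressWarnings(as.integer(tab$arg))
  .nci_cache$templates <- tab
  tab
}

empty_features <- function() {
  structure(list(
    donors = data.frame(serial = integer(0), no_h = logical(0),
                        resname = character(0), chain = character(0),
                        resseq = integer(0), icode = character(0),
                        h_serials = I(list())),
    acceptors = data.frame(serial = integer(0), y_serial = integer(0),
                           resname = character(0), chain = character(0),
                           resseq = integer(0), icode = character(0)),
    pos_centers = data.frame(cx = numeric(0), cy = numeric(0), cz = numeric(0),
                             kind = character(0), resname = character(0),
                             chain = character(0), resseq = integer(0),
                             icode = character(0), serials = I(list())),
    neg_centers = data.frame(cx = numeric(0), cy = numeric(0), cz = numeric(0),
                             kind = character(0), resname = character(0),
                             chain = character(0), resseq = integer(0),
                             icode = character(0), serials = I(list())),
    rings = data.frame(cx = numeric(0), cy = numeric(0), cz = numeric(0),
                       nx = numeric(0), ny = numeric(0), nz = numeric(0),
                       rmsd = numeric(0), label = character(0),
                       group = character(0), resname = character(0),
                       chain = character(0), resseq = integer(0),
                       icode = character(0), serials = I(list())),
    hydrophobics = data.frame(serial = integer(0), resname = character(0),
                              chain = character(0), resseq = integer(0),
                              icode = character(0)),
    halogen_donors = data.frame(x_serial = integer(0), c_serial = integer(0),
                                resname = character(0), chain = character(0),
                                resseq = integer(0), icode = character(0)),
    metals = data.frame(serial = integer(0), element = character(0),
                        resname = character(0), chain = character(0),
                        resseq = integer(0), icode = character(0)),
    waters = data.frame(serial = integer(0), resname = character(0),
                        chain = character(0), resseq = integer(0),
                        icode = character(0))
  ), class = "nci_features")
}

bind_features <- function(a, b) {
  for (k in names(a)) a[[k]] <- rbind(a[[k]], b[[k]])
  a
}

res_meta <- function(res_atoms, n = 1) {
  data.frame(resname = rep(res_atoms$resname[1], n),
             chain = rep(res_atoms$chain[1], n),
             resseq = rep(res_atoms$resseq[1], n),
             icode = rep(res_atoms$icode[1], n),
             stringsAsFactors = FALSE)
}

atom_serial_by_name <- function(res_atoms, name) {
  i <- which(res_atoms$name == name)
  if (length(i)) res_atoms$serial[i[1]] else NA_integer_
}

make_ring <- function(res_atoms, serials, label, group, meta) {
  pts <- as.matrix(res_atoms[match(serials, res_atoms$serial), c("x", "y", "z")])
  if (nrow(pts) < 4) return(NULL)
  pl <- fit_plane(pts)
  if (pl$rmsd > RING_PLANARITY_RMSD_MAX) return(NULL)
  cbind(data.frame(cx = pl$centroid[1], cy = pl$centroid[2], cz = pl$centroid[3],
                   nx = pl$normal[1], ny = pl$normal[2], nz = pl$normal[3],
                   rmsd = pl$rmsd, label = label, group = group,
                   stringsAsFactors = FALSE),
        meta, data.frame(serials = I(list(serials))))
}

make_center <- function(res_atoms, serials, kind, meta) {
  pts <- as.matrix(res_atoms[match(serials, res_atoms$serial), c("x", "y", "z")])
  ctr <- colMeans(pts)
  cbind(data.frame(cx = ctr[1], cy = ctr[2], cz = ctr[3], kind = kind,
                   stringsAsFactors = FALSE),
        meta, data.frame(serials = I(list(serials))))
}

# features of one standard residue (amino acid or nucleotide) via templates
template_features <- function(res_atoms, kind, all_atoms) {
  tmpl <- load_templates()
  rn <- res_atoms$resname[1]
  rows <- tmpl[tmpl$residue == rn, , drop = FALSE]
  f <- empty_features()
  meta1 <- res_meta(res_atoms)
  bonds <- perceive_bonds(res_atoms)

  donor_rows <- rows[rows$feature == "donor", , drop = FALSE]
  if (kind == "amino_acid" && rn != "PRO")
    donor_rows <- rbind(donor_rows,
                        data.frame(residue = rn, atom = "N", feature = "donor",
                                   arg = 1L))
  for (i in seq_len(nrow(donor_rows))) {
    s <- atom_serial_by_name(res_atoms, donor_rows$atom[i])
    if (is.na(s)) next
    hs <- attached_hydrogens(res_atoms, s)
    f$donors <- rbind(f$donors, cbind(
      data.frame(serial = s, no_h = length(hs) == 0), meta1,
      data.frame(h_serials = I(list(hs)))))
  }

  acc_names <- rows$atom[rows$feature == "acceptor"]
  if (kind == "amino_acid") acc_names <- c(acc_names, "O", "OXT")
  for (nm in acc_names) {
    s <- atom_serial_by_name(res_atoms, nm)
    if (is.na(s)) next
    nb <- heavy_neighbors(res_atoms, s, bonds)
    f$acceptors <- rbind(f$acceptors, cbind(
      data.frame(serial = s,
                 y_serial = if (length(nb)) nb[1] else NA_integer_), meta1))
  }

  neg_names <- rows$atom[rows$feature == "neg"]
  neg_serials <- stats::na.omit(vapply(neg_names, atom_serial_by_name,
                                       integer(1), res_atoms = res_atoms))
  if (length(neg_serials))
    f$neg_centers <- rbind(f$neg_centers,
                           make_center(res_atoms, as.integer(neg_serials),
                                       if (kind == "amino_acid") "carboxylate"
                                       else "phosphate", meta1))

  pos_names <- rows$atom[rows$feature == "pos"]
  pos_serials <- stats::na.omit(vapply(pos_names, atom_serial_by_name,
                                       integer(1), res_atoms = res_atoms))
  if (length(pos_serials))
    f$pos_centers <- rbind(f$pos_centers,
                           make_center(res_atoms, as.integer(pos_serials),
                                       if (rn == "ARG") "guanidinium" else "amine",
                                       meta1))
  # His counts as cationic only when both ring nitrogens are protonated
  if (rn == "HIS") {
    nd1 <- atom_serial_by_name(res_atoms, "ND1")
    ne2 <- atom_serial_by_name(res_atoms, "NE2")
    if (!is.na(nd1) && !is.na(ne2) &&
        length(attached_hydrogens(res_atoms, nd1)) > 0 &&
        length(attached_hydrogens(res_atoms, ne2)) > 0) {
      ring_serials <- stats::na.omit(vapply(
        rows$atom[rows$feature == "ring1"], atom_serial_by_name, integer(1),
        res_atoms = res_atoms))
      f$pos_centers <- rbind(f$pos_centers,
                             make_center(res_atoms, as.integer(ring_serials),
                                         "imidazolium", meta1))
      # a protonated ND1 is no longer an acceptor
      f$acceptors <- f$acceptors[f$acceptors$serial != nd1, , drop = FALSE]
    }
  }

  group_id <- paste(res_atoms$chain[1], res_atoms$resseq[1],
                    res_atoms$icode[1], rn, sep = ":")
  ring_sets <- list()
  for (rg in c("ring1", "ring2")) {
    nms <- rows$atom[rows$feature == rg]
    if (!length(nms)) next
    ser <- stats::na.omit(vapply(nms, atom_serial_by_name, integer(1),
                                 res_atoms = res_atoms))
    if (length(ser) < length(nms)) next
    ring_sets[[rg]] <- as.integer(ser)
    r <- make_ring(res_atoms, as.integer(ser),
                   sprintf("%d-ring", length(ser)), group_id, meta1)
    if (!is.null(r)) f$rings <- rbind(f$rings, r)
  }
  if (length(ring_sets) == 2) {
    fused <- unique(unlist(ring_sets))
    r <- make_ring(res_atoms, fused, "fused", group_id, meta1)
    if (!is.null(r)) f$rings <- rbind(f$rings, r)
  }

  hyd_names <- rows$atom[rows$feature == "hydrophobic"]
  hyd <- stats::na.omit(vapply(hyd_names, atom_serial_by_name, integer(1),
                               res_atoms = res_atoms))
  if (length(hyd))
    f$hydrophobics <- rbind(f$hydrophobics,
                            cbind(data.frame(serial = as.integer(hyd)),
                                  res_meta(res_atoms, length(hyd))))
  f
}

# bounded smallest-ring search: all unique 5/6-membered cycles
find_small_rings <- function(serials, bonds) {
  adj <- lapply(serials, function(s) bond_neighbors(s, bonds))
  names(adj) <- as.character(serials)
  rings <- list()
  edges <- bonds[bonds$from %in% serials & bonds$to %in% serials, , drop = FALSE]
  for (i in seq_len(nrow(edges))) {
    u <- edges$from[i]; v <- edges$to[i]
    # BFS from u to v excluding the direct edge, depth <= 5
    prev <- list(); prev[[as.character(u)]] <- NA
    frontier <- u; depth <- 0; found <- FALSE
    while (length(frontier) && depth < 5 && !found) {
      nxt <- integer(0)
      for (w in frontier) {
        for (nb in adj[[as.character(w)]]) {
          if (w == u && nb == v) next
          if (!is.null(prev[[as.character(nb)]])) next
          if (!(nb %in% serials)) next
          prev[[as.character(nb)]] <- w
          if (nb == v) { found <- TRUE; break }
          nxt <- c(nxt, nb)
        }
        if (found) break
      }
      frontier <- nxt; depth <- depth + 1
    }
    if (found) {
      path <- v
      w <- v
      while (!is.na(prev[[as.character(w)]])) {
        w <- prev[[as.character(w)]]
        path <- c(path, w)
      }
      if (length(path) %in% c(5, 6))
        rings[[length(rings) + 1]] <- sort(path)
    }
  }
  unique(rings)
}

# generic perception for hetero entities from element/valence/bond rules
generic_features <- function(atoms, conect = NULL, mode = analysis_mode()) {
  f <- empty_features()
  if (!nrow(atoms)) return(f)
  bonds <- perceive_bonds(atoms, conect)
  heavy <- atoms[atoms$element != "H", , drop = FALSE]
  meta_for <- function(i, n = 1) {
    data.frame(resname = rep(heavy$resname[i], n), chain = rep(heavy$chain[i], n),
               resseq = rep(heavy$resseq[i], n), icode = rep(heavy$icode[i], n),
               stringsAsFactors = FALSE)
  }
  deg <- vapply(heavy$serial, function(s)
    length(heavy_neighbors(atoms, s, bonds)), integer(1))
  nh <- vapply(heavy$serial, function(s)
    length(attached_hydrogens(atoms, s, bonds)), integer(1))
  el <- heavy$element
  is_metal <- toupper(el) %in% METAL_ELEMENTS_DEFAULT |
    el %in% c("Na", "Mg", "Ca", "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Cd", "K")

  pos_member <- rep(FALSE, nrow(heavy))   # atoms already in a positive group

  # ring membership first: an aromatic amidine carbon (e.g. a nucleobase C
  # flanked by ring nitrogens) is not a guanidinium centre
  cyc <- find_small_rings(heavy$serial, bonds)
  ring_atoms <- unique(unlist(cyc))

  for (i in seq_len(nrow(heavy))) {
    s <- heavy$serial[i]
    if (is_metal[i]) {
      f$metals <- rbind(f$metals, cbind(data.frame(serial = s, element = el[i]),
                                        meta_for(i)))
      next
    }
    nb <- heavy_neighbors(atoms, s, bonds)
    nb_el <- heavy$element[match(nb, heavy$serial)]
    nb_deg <- deg[match(nb, heavy$serial)]

    # charged groups seeded at the central atom
    if (el[i] == "C" && sum(nb_el == "O" & nb_deg == 1) == 2 && deg[i] <= 3) {
      oxy <- nb[nb_el == "O" & nb_deg == 1]
      f$neg_centers <- rbind(f$neg_centers,
                             make_center(heavy, oxy, "carboxylate", meta_for(i)))
    }
    if (el[i] %in% c("P", "S") && sum(nb_el == "O" & nb_deg == 1) >= 2) {
      oxy <- nb[nb_el == "O" & nb_deg == 1]
      f$neg_centers <- rbind(f$neg_centers,
                             make_center(heavy, oxy,
                                         if (el[i] == "P") "phosphate" else "sulfonate",
                                         meta_for(i)))
    }
    if (el[i] == "C" && deg[i] == 3 && all(nb_el == "N") &&
        all(nb_deg <= 2) && !(s %in% ring_atoms)) {
      f$pos_centers <- rbind(f$pos_centers,
                             make_center(heavy, c(s, nb), "guanidinium",
                                         meta_for(i)))
      pos_member[match(nb, heavy$serial)] <- TRUE
    }
  }
  for (i in seq_len(nrow(heavy))) {
    s <- heavy$serial[i]
    if (is_metal[i]) next
    if (el[i] == "N" && !pos_member[i] && (nh[i] >= 3 || deg[i] == 4)) {
      f$pos_centers <- rbind(f$pos_centers,
                             make_center(heavy, s, "amine", meta_for(i)))
      pos_member[i] <- TRUE
    }
    # halide anion: lone halogen atom
    if (el[i] %in% c("F", "Cl", "Br", "I") && deg[i] == 0)
      f$neg_centers <- rbind(f$neg_centers,
                             make_center(heavy, s, "halide", meta_for(i)))
  }

  for (i in seq_len(nrow(heavy))) {
    s <- heavy$serial[i]
    if (is_metal[i]) next
    nb <- heavy_neighbors(atoms, s, bonds)
    nb_el <- heavy$element[match(nb, heavy$serial)]
    hs <- attached_hydrogens(atoms, s, bonds)

    if (el[i] %in% c("N", "O", "S") && length(hs) > 0)
      f$donors <- rbind(f$donors, cbind(
        data.frame(serial = s, no_h = FALSE), meta_for(i),
        data.frame(h_serials = I(list(hs)))))
    # potential donor without placeable hydrogen: terminal amine-like N
    if (el[i] == "N" && length(hs) == 0 && deg[i] <= 1 && !pos_member[i])
      f$donors <- rbind(f$donors, cbind(
        data.frame(serial = s, no_h = TRUE), meta_for(i),
        data.frame(h_serials = I(list(integer(0))))))

    acc <- FALSE
    if (el[i] == "O" && deg[i] <= 2) acc <- TRUE
    if (el[i] == "N" && deg[i] + nh[i] <= 2) acc <- TRUE
    if (el[i] == "N" && (deg[i] == 4 || pos_member[i])) acc <- FALSE
    if (acc)
      f$acceptors <- rbind(f$acceptors, cbind(
        data.frame(serial = s, y_serial = if (length(nb)) nb[1] else NA_integer_),
        meta_for(i)))

    if (el[i] %in% c("Cl", "Br", "I") ||
        (el[i] == "F" && isTRUE(mode$halogen_include_fluorine))) {
      cn <- nb[nb_el == "C"]
      if (length(cn) == 1 && deg[i] == 1)
        f$halogen_donors <- rbind(f$halogen_donors, cbind(
          data.frame(x_serial = s, c_serial = cn), meta_for(i)))
    }

    if (el[i] == "C" && (length(nb) == 0 || all(nb_el == "C")))
      f$hydrophobics <- rbind(f$hydrophobics,
                              cbind(data.frame(serial = s), meta_for(i)))
  }

  # rings: 5/6-cycles (found above), C/N/O/S members, sp2-ish, planar
  seen_groups <- list()
  ring_rows <- list()
  for (ring in cyc) {
    idx <- match(ring, heavy$serial)
    if (any(is.na(idx))) next
    if (!all(heavy$element[idx] %in% c("C", "N", "O", "S"))) next
    if (!all(deg[idx] + nh[idx] <= 3)) next
    grp <- heavy$serial[idx[1]]  # provisional; fused groups merged below
    ring_rows[[length(ring_rows) + 1]] <- list(serials = ring)
  }
  if (length(ring_rows)) {
    sets <- lapply(ring_rows, `[[`, "serials")
    # merge rings sharing >= 2 atoms into fused groups
    grp_id <- seq_along(sets)
    repeat {
      changed <- FALSE
      for (a in seq_along(sets)) for (b in seq_along(sets)) {
        if (a < b && length(intersect(sets[[a]], sets[[b]])) >= 2 &&
            grp_id[a] != grp_id[b]) {
          grp_id[grp_id == grp_id[b]] <- grp_id[a]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (g in unique(grp_id)) {
      members <- sets[grp_id == g]
      gid <- paste0("het:", min(unlist(members)))
      for (ring in members) {
        i0 <- match(ring[1], heavy$serial)
        r <- make_ring(heavy, ring, sprintf("%d-ring", length(ring)), gid,
                       meta_for(i0))
        if (!is.null(r)) f$rings <- rbind(f$rings, r)
      }
      if (length(members) > 1) {
        fused <- sort(unique(unlist(members)))
        i0 <- match(fused[1], heavy$serial)
        r <- make_ring(heavy, fused, "fused", gid, meta_for(i0))
        if (!is.null(r)) f$rings <- rbind(f$rings, r)
      }
    }
  }
  f
}

#' Perceive chemical features of a set of atoms
#'
#' Splits the atoms by residue; standard amino acids and nucleotides are
#' characterised from the shipped name-based templates, waters and metal ions
#' are registered directly, and everything else goes through generic
#' element/valence/bond-rule perception (CONECT records, when present, are
#' honoured during bond perception).
#'
#' @param atoms atom data frame (one side of an analysis, hydrogens included)
#' @param conect optional CONECT edge list
#' @param mode an [analysis_mode()]
#' @return an `nci_features` object: data frames `donors`, `acceptors`,
#'   `pos_centers`, `neg_centers`, `rings`, `hydrophobics`, `halogen_donors`,
#'   `metals`, `waters`
#' @export
perceive_features <- function(atoms, conect = NULL, mode = analysis_mode()) {
  f <- empty_features()
  if (!nrow(atoms)) return(f)
  keys <- res_key(atoms)
  generic_pool <- atoms[0, , drop = FALSE]
  for (k in unique(keys)) {
    res_atoms <- atoms[keys == k, , drop = FALSE]
    kind <- residue_kind(res_atoms$resname[1])
    if (kind %in% c("amino_acid", "dna", "rna")) {
      f <- bind_features(f, template_features(res_atoms, kind, atoms))
    } else if (kind == "water") {
      o <- res_atoms[res_atoms$element == "O", , drop = FALSE]
      if (nrow(o))
        f$waters <- rbind(f$waters, cbind(data.frame(serial = o$serial[1]),
                                          res_meta(res_atoms)))
    } else if (kind == "metal_ion") {
      m <- res_atoms[res_atoms$element != "H", , drop = FALSE]
      f$metals <- rbind(f$metals, cbind(
        data.frame(serial = m$serial[1], element = m$element[1]),
        res_meta(res_atoms)))
    } else {
      generic_pool <- rbind(generic_pool, res_atoms)
    }
  }
  if (nrow(generic_pool))
    f <- bind_features(f, generic_features(generic_pool, conect, mode))
  f
}
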