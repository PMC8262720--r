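# Covalent topology. Bonds come from CONECT records where present, plus
# distance-based perception (sum of covalent radii + 0.45 A tolerance) for
# everything else. Detectors only ever need local topology (attached heavy
# atoms, attached hydrogens), so perception is run on small atom subsets.

COVALENT_RADII <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
  F = 0.57, Cl = 1.02, Br = 1.20, I = 1.39, Se = 1.20, B = 0.84,
  Na = 1.66, K = 2.03, Mg = 1.41, Ca = 1.76, Mn = 1.39, Fe = 1.32,
  Co = 1.26, Ni = 1.24, Cu = 1.32, Zn = 1.22, Cd = 1.44, X = 0.77
)

cov_radius <- function(element) {
  r <- COVALENT_RADII[element]
  r[is.na(r)] <- 0.77
  unname(r)
}

#' Perceive covalent bonds among a set of atoms
#'
#' Returns an undirected edge list of atom serials. CONECT records (if given)
#' are taken verbatim; additional bonds are inferred wherever the
#' inter-atomic distance is below the sum of covalent radii plus 0.45 A.
#' Metals are never bonded by the distance rule (their contacts are
#' coordination, not covalence).
#'
#' @param atoms atom data frame (rows of a structure's atom table)
#' @param conect optional CONECT edge data frame with serial columns from/to
#' @return data.frame(from, to) of atom serials, from < to
#' @export
perceive_bonds <- function(atoms, conect = NULL) {
  n <- nrow(atoms)
  edges <- matrix(integer(0), ncol = 2)
  if (n >= 2) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    d <- cross_dist(xyz, xyz)
    r <- cov_radius(atoms$element)
    lim <- outer(r, r, "+") + 0.45
    is_metal <- toupper(atoms$element) %in% METAL_ELEMENTS_DEFAULT |
      atoms$element %in% c("Na", "Mg", "Ca", "Mn", "Fe", "Co", "Ni", "Cu",
                           "Zn", "Cd", "K")
    ok <- d > 0.3 & d <= lim
    ok[is_metal, ] <- FALSE
    ok[, is_metal] <- FALSE
    ok[lower.tri(ok, diag = TRUE)] <- FALSE
    idx <- which(ok, arr.ind = TRUE)
    if (nrow(idx)) {
      edges <- cbind(atoms$serial[idx[, 1]], atoms$serial[idx[, 2]])
    }
  }
  out <- data.frame(from = pmin(edges[, 1], edges[, 2]),
                    to = pmax(edges[, 1], edges[, 2]))
  if (!is.null(conect) && nrow(conect)) {
    keep <- conect$from %in% atoms$serial & conect$to %in% atoms$serial
    out <- rbind(out, conect[keep, c("from", "to")])
  }
  out <- unique(out)
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Neighbour serials of one atom in a bond edge list
bond_neighbors <- function(serial, bonds) {
  c(bonds$to[bonds$from == serial], bonds$from[bonds$to == serial])
}

# Attached hydrogens of a heavy atom: bonded H, or any H within 1.3 A
attached_hydrogens <- function(atoms, heavy_serial, bonds = NULL) {
  h <- atoms[atoms$element == "H", , drop = FALSE]
  if (!nrow(h)) return(integer(0))
  ha <- atoms[atoms$serial == heavy_serial, , drop = FALSE]
  if (!nrow(ha)) return(integer(0))
  d <- cross_dist(as.matrix(ha[, c("x", "y", "z")]),
                  as.matrix(h[, c("x", "y", "z")]))
  h$serial[d[1, ] <= 1.3]
}

# Heavy-atom neighbours by bond list, falling back to distance perception
heavy_neighbors <- function(atoms, serial, bonds) {
  nb <- bond_neighbors(serial, bonds)
  nb_atoms <- atoms[atoms$serial %in% nb, , drop = FALSE]
  nb_atoms$serial[nb_atoms$element != "H"]
}
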