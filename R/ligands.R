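#' @title Complex preparation
#'
#' @description
#' Splits a structure into receptor and ligand entities and builds per-ligand
#' binding sites. Hetero residues not on the exclusion list become ligand
#' entities; covalently connected hetero residues are merged into one
#' composite entity. Nucleic residues are either receptor (nucleic-receptor
#' mode) or grouped into per-chain nucleic ligand entities. Waters are never
#' ligand entities: they mediate water bridges instead.
#'
#' @name complex-preparation
NULL

COVALENT_MERGE_DIST <- 1.9

new_ligand <- function(atoms, kind, composite = FALSE) {
  heavy <- atoms[atoms$element != "H", , drop = FALSE]
  ord <- order(heavy$chain, heavy$resseq, heavy$icode)
  prim <- heavy[ord[1], ]
  structure(list(
    atoms = atoms,
    residue_keys = unique(res_key(atoms)),
    kind = kind,
    composite = composite,
    identifier = sprintf("%s:%s:%d%s", prim$resname, prim$chain,
                         prim$resseq, prim$icode),
    resname = prim$resname, chain = prim$chain,
    resseq = prim$resseq, icode = prim$icode
  ), class = "nci_ligand")
}

#' @export
print.nci_ligand <- function(x, ...) {
  cat(sprintf("<nci_ligand> %s (%s, %d residue(s), %d heavy atoms%s)\n",
              x$identifier, x$kind, length(x$residue_keys),
              sum(x$atoms$element != "H"),
              if (x$composite) ", composite" else ""))
  invisible(x)
}

# minimum heavy-atom distance between two residue atom tables
min_heavy_dist <- function(a, b) {
  a <- a[a$element != "H", , drop = FALSE]
  b <- b[b$element != "H", , drop = FALSE]
  if (!nrow(a) || !nrow(b)) return(Inf)
  min(cross_dist(as.matrix(a[, c("x", "y", "z")]),
                 as.matrix(b[, c("x", "y", "z")])))
}

residue_conect_linked <- function(a, b, conect) {
  if (is.null(conect) || !nrow(conect)) return(FALSE)
  any((conect$from %in% a$serial & conect$to %in% b$serial) |
        (conect$from %in% b$serial & conect$to %in% a$serial))
}

#' Extract ligand entities from a structure
#'
#' Hetero residues not on the mode's exclusion list become ligand entities.
#' Covalently connected hetero residues (CONECT, or any inter-residue
#' heavy-atom distance below 1.9 A) are merged into one composite entity.
#' When `mode$nucleic_acids_as_receptor` is TRUE, DNA/RNA residues are
#' removed from ligand candidacy (they join the receptor); when FALSE, each
#' contiguous nucleic chain becomes one `nucleic_chain` entity. HETATM
#' residues covalently linked into a polymer chain (modified residues) stay
#' with the receptor unless `mode$modified_residues_as_ligand` is set. A lone
#' metal ion becomes an entity of kind `ion`. A structure with no hetero
#' content yields an empty list (an advisory message, not an error).
#'
#' @param s an `nci_structure` (model selected, hydrogens ensured)
#' @param mode an [analysis_mode()]
#' @return list of `nci_ligand` entities
#' @export
extract_ligands <- function(s, mode = analysis_mode()) {
  atoms <- structure_atoms(s)
  keys <- res_key(atoms)
  ukeys <- unique(keys)
  kinds <- residue_kind(vapply(strsplit(ukeys, ":", fixed = TRUE),
                               function(p) p[[4]], character(1)))
  res_list <- lapply(ukeys, function(k) atoms[keys == k, , drop = FALSE])
  names(res_list) <- ukeys

  ligands <- list()

  # nucleic chains as ligands (unless they are receptor)
  nuc_idx <- which(kinds %in% c("dna", "rna"))
  if (!mode$nucleic_acids_as_receptor && length(nuc_idx)) {
    nuc_keys <- ukeys[nuc_idx]
    meta <- do.call(rbind, lapply(nuc_keys, function(k) {
      r <- res_list[[k]]
      data.frame(key = k, chain = r$chain[1], resseq = r$resseq[1],
                 stringsAsFactors = FALSE)
    }))
    for (ch in unique(meta$chain)) {
      sub <- meta[meta$chain == ch, , drop = FALSE]
      sub <- sub[order(sub$resseq), , drop = FALSE]
      # split chain into contiguous runs (backbone O3'-P link when computable,
      # otherwise consecutive numbering)
      run <- 1L
      runs <- integer(nrow(sub))
      runs[1] <- run
      if (nrow(sub) > 1) for (i in 2:nrow(sub)) {
        a <- res_list[[sub$key[i - 1]]]
        b <- res_list[[sub$key[i]]]
        o3 <- a[a$name == "O3'", , drop = FALSE]
        p <- b[b$name == "P", , drop = FALSE]
        linked <- if (nrow(o3) && nrow(p)) {
          dist3(as.numeric(o3[1, c("x", "y", "z")]),
                as.numeric(p[1, c("x", "y", "z")])) <= 2.5
        } else sub$resseq[i] - sub$resseq[i - 1] <= 1
        if (!linked) run <- run + 1L
        runs[i] <- run
      }
      for (r in unique(runs)) {
        ks <- sub$key[runs == r]
        lat <- do.call(rbind, res_list[ks])
        ligands[[length(ligands) + 1]] <-
          new_ligand(lat, "nucleic_chain", composite = length(ks) > 1)
      }
    }
  }

  # hetero residues
  het_idx <- which(kinds %in% c("metal_ion", "other_hetero"))
  het_keys <- ukeys[het_idx]
  resname_of <- function(k) strsplit(k, ":", fixed = TRUE)[[1]][4]
  het_keys <- het_keys[!(vapply(het_keys, resname_of, character(1)) %in%
                           mode$ligand_exclusion_list)]

  # modified residues: hetero covalently linked into a polymer chain
  polymer_keys <- ukeys[kinds %in% c("amino_acid", "dna", "rna")]
  is_modified <- vapply(het_keys, function(k) {
    r <- res_list[[k]]
    any(vapply(polymer_keys, function(pk)
      min_heavy_dist(r, res_list[[pk]]) < COVALENT_MERGE_DIST ||
        residue_conect_linked(r, res_list[[pk]], s$conect), logical(1)))
  }, logical(1))
  if (!mode$modified_residues_as_ligand && length(het_keys))
    het_keys <- het_keys[!is_modified]

  if (length(het_keys)) {
    # merge covalently connected hetero residues (union-find)
    n <- length(het_keys)
    grp <- seq_len(n)
    if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
      a <- res_list[[het_keys[i]]]; b <- res_list[[het_keys[j]]]
      if (min_heavy_dist(a, b) < COVALENT_MERGE_DIST ||
          residue_conect_linked(a, b, s$conect))
        grp[grp == grp[j]] <- grp[i]
    }
    for (g in unique(grp)) {
      ks <- het_keys[grp == g]
      lat <- do.call(rbind, res_list[ks])
      heavy <- lat[lat$element != "H", , drop = FALSE]
      kind <- if (length(ks) == 1 && nrow(heavy) == 1 &&
                  toupper(heavy$element[1]) %in% METAL_ELEMENTS_DEFAULT)
        "ion" else "small_molecule"
      ligands[[length(ligands) + 1]] <-
        new_ligand(lat, kind, composite = length(ks) > 1)
    }
  }

  if (!length(ligands))
    message("no ligand entities found (no hetero or nucleic ligand content)")
  # deterministic order: chain, then sequence number
  ord <- order(vapply(ligands, function(l) l$chain, character(1)),
               vapply(ligands, function(l) l$resseq, integer(1)))
  ligands[ord]
}

#' Build the binding site of a ligand entity
#'
#' Receptor residues are all non-ligand, non-water residues with at least one
#' heavy atom within `cutoff` of any ligand heavy atom. Residues belonging to
#' other ligand entities can be excluded via `exclude_keys`.
#'
#' @param s an `nci_structure`
#' @param lig an `nci_ligand`
#' @param cutoff site-shell distance in Angstrom
#'   (default `binding_site_dist`)
#' @param exclude_keys residue keys never admitted to the receptor
#'   (typically the residues of all other ligand entities)
#' @return an `nci_site`: ligand, receptor atom table and per-kind residue
#'   summary; an empty site (no receptor atoms in range) is valid and is
#'   reported as "no contacts"
#' @export
build_binding_site <- function(s, lig, cutoff = default_config()$binding_site_dist,
                               exclude_keys = character(0)) {
  stopifnot(cutoff > 0)
  atoms <- structure_atoms(s)
  keys <- res_key(atoms)
  lig_keys <- lig$residue_keys
  cand <- !(keys %in% c(lig_keys, exclude_keys)) &
    residue_kind(atoms$resname) != "water"
  rec <- atoms[cand, , drop = FALSE]
  rec_heavy <- rec[rec$element != "H", , drop = FALSE]
  lig_heavy <- lig$atoms[lig$atoms$element != "H", , drop = FALSE]
  keep_keys <- character(0)
  if (nrow(rec_heavy) && nrow(lig_heavy)) {
    d <- cross_dist(as.matrix(rec_heavy[, c("x", "y", "z")]),
                    as.matrix(lig_heavy[, c("x", "y", "z")]))
    hit <- apply(d, 1, min) <= cutoff
    keep_keys <- unique(res_key(rec_heavy)[hit])
  }
  rec_atoms <- atoms[keys %in% keep_keys, , drop = FALSE]
  kindtab <- residue_kind(vapply(strsplit(keep_keys, ":", fixed = TRUE),
                                 function(p) p[[4]], character(1)))
  structure(list(
    ligand = lig,
    receptor_atoms = rec_atoms,
    receptor_keys = keep_keys,
    receptor_kind_summary = c(
      amino_acid = sum(kindtab == "amino_acid"),
      dna = sum(kindtab == "dna"),
      rna = sum(kindtab == "rna"),
      other = sum(!kindtab %in% c("amino_acid", "dna", "rna"))),
    cutoff = cutoff
  ), class = "nci_site")
}

#' Restrict a binding site to inter-chain partners
#'
#' When intra-chain analysis is disabled and the ligand is a polymer entity
#' (peptide or nucleic chain), receptor residues on the ligand's own chain
#' are removed. For small-molecule and ion ligands the rule does not apply
#' and the site is returned unchanged.
#'
#' @param site an `nci_site`
#' @param mode an [analysis_mode()]
#' @return the (possibly filtered) site
#' @export
classify_receptor_scope <- function(site, mode = analysis_mode()) {
  if (mode$intra_chain) return(site)
  if (!site$ligand$kind %in% c("peptide", "nucleic_chain")) return(site)
  lig_chains <- unique(site$ligand$atoms$chain)
  keep <- !(site$receptor_atoms$chain %in% lig_chains)
  site$receptor_atoms <- site$receptor_atoms[keep, , drop = FALSE]
  site$receptor_keys <- unique(res_key(site$receptor_atoms))
  kindtab <- residue_kind(vapply(strsplit(site$receptor_keys, ":", fixed = TRUE),
                                 function(p) p[[4]], character(1)))
  site$receptor_kind_summary <- c(
    amino_acid = sum(kindtab == "amino_acid"),
    dna = sum(kindtab == "dna"),
    rna = sum(kindtab == "rna"),
    other = sum(!kindtab %in% c("amino_acid", "dna", "rna")))
  site
}

#' @export
print.nci_site <- function(x, ...) {
  cat(sprintf("<nci_site> ligand %s: %d receptor residue(s) within %.1f A\n",
              x$ligand$identifier, length(x$receptor_keys), x$cutoff))
  s <- x$receptor_kind_summary
  cat("  receptor composition:",
      paste(sprintf("%s=%d", names(s), s), collapse = ", "), "\n")
  invisible(x)
}
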