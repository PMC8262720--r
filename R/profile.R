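#' Profile the non-covalent interactions of a macromolecular complex
#'
#' The main entry point. Runs the four pipeline stages on a PDB-format
#' structure: (1) structure preparation (parsing, model selection,
#' hydrogenation), (2) ligand and binding-site extraction, (3) functional
#' characterisation of ligand and receptor atoms, and (4) rule-based
#' matching and filtering of the eight interaction classes.
#'
#' @param input path to a PDB file, a character vector of PDB lines, or an
#'   already parsed `nci_structure`
#' @param config an `nci_config` of geometric thresholds
#'   (see [default_config()])
#' @param mode an [analysis_mode()] (nucleic-receptor flag, intra-chain
#'   scope, modified-residue handling, ligand exclusion list)
#' @param model which model of a multi-model structure to analyse (default 1)
#' @return an object of class `nci_profile`: the hydrogenated structure, the
#'   effective config and mode, the hydrogenation report, and one entry per
#'   binding site holding the ligand, the site and its refined interaction
#'   table
#' @export
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' generate_fixture(list(plant("hbond", dist = 2.9, angle = 165)), f)
#' p <- profile_complex(f)
#' summary(p)
profile_complex <- function(input, config = default_config(),
                            mode = analysis_mode(), model = 1) {
  validate_config(config)
  s <- if (inherits(input, "nci_structure")) input else parse_pdb(input)
  s <- select_model(s, model)
  hy <- ensure_hydrogens(s)
  s <- hy$structure

  ligs <- suppressMessages(extract_ligands(s, mode))
  all_lig_keys <- unlist(lapply(ligs, function(l) l$residue_keys))
  atoms <- structure_atoms(s)

  water_atoms <- atoms[residue_kind(atoms$resname) == "water" &
                         atoms$element == "O", , drop = FALSE]

  sites <- lapply(ligs, function(lig) {
    site <- build_binding_site(s, lig, config$binding_site_dist,
                               exclude_keys = setdiff(all_lig_keys,
                                                      lig$residue_keys))
    site <- classify_receptor_scope(site, mode)
    waters <- NULL
    if (nrow(water_atoms)) {
      lig_heavy <- lig$atoms[lig$atoms$element != "H", , drop = FALSE]
      d <- cross_dist(as.matrix(water_atoms[, c("x", "y", "z")]),
                      as.matrix(lig_heavy[, c("x", "y", "z")]))
      near <- apply(d, 1, min) <= config$binding_site_dist
      w <- water_atoms[near, , drop = FALSE]
      if (nrow(w))
        waters <- data.frame(serial = w$serial, resname = w$resname,
                             chain = w$chain, resseq = w$resseq,
                             icode = w$icode, stringsAsFactors = FALSE)
    }
    inter <- detect_interactions(site, atoms, waters, config, mode, s$conect)
    list(ligand = lig, site = site, waters = waters, interactions = inter)
  })
  # deterministic site order: ligand chain, then sequence number
  if (length(sites)) {
    ord <- order(vapply(sites, function(x) x$ligand$chain, character(1)),
                 vapply(sites, function(x) x$ligand$resseq, integer(1)),
                 vapply(sites, function(x) x$ligand$identifier, character(1)))
    sites <- sites[ord]
  }

  structure(list(
    structure = s,
    input = if (is.character(input) && length(input) == 1 &&
                file.exists(input)) normalizePath(input) else "<text>",
    header_id = s$header_id,
    config = config,
    mode = mode,
    hydrogen_report = hy$report,
    sites = sites,
    version = as.character(utils::packageVersion("nciprofiler"))
  ), class = "nci_profile")
}

#' Per-type interaction counts of a profile
#'
#' @param object an `nci_profile`
#' @param by_chain also return counts keyed by receptor chain
#' @param ... unused
#' @return list with `total` (named count per interaction type), `per_site`
#'   (matrix site x type) and, when `by_chain`, `per_chain`
#'   (matrix receptor-chain x type)
#' @export
summarize_profile <- function(object, by_chain = TRUE, ...) {
  types <- INTERACTION_TYPES
  per_site <- t(vapply(object$sites, function(s) {
    tab <- table(factor(s$interactions$type, levels = types))
    as.integer(tab)
  }, integer(length(types))))
  if (!length(object$sites))
    per_site <- matrix(0L, 0, length(types))
  colnames(per_site) <- types
  rownames(per_site) <- vapply(object$sites,
                               function(s) s$ligand$identifier, character(1))
  total <- colSums(per_site)
  out <- list(total = total, per_site = per_site)
  if (by_chain) {
    all_int <- do.call(rbind, c(list(empty_interactions()),
                                lapply(object$sites, `[[`, "interactions")))
    chains <- sort(unique(all_int$rec_chain))
    per_chain <- matrix(0L, length(chains), length(types),
                        dimnames = list(chains, types))
    for (i in seq_len(nrow(all_int)))
      per_chain[all_int$rec_chain[i], all_int$type[i]] <-
        per_chain[all_int$rec_chain[i], all_int$type[i]] + 1L
    out$per_chain <- per_chain
  }
  out
}

#' All interactions of a profile as one data frame
#'
#' @param p an `nci_profile`
#' @return interaction data frame with an extra `site` column
#' @export
profile_interactions <- function(p) {
  if (!length(p$sites)) return(cbind(empty_interactions(),
                                     site = character(0)))
  do.call(rbind, lapply(p$sites, function(s) {
    if (!nrow(s$interactions))
      return(cbind(empty_interactions(), site = character(0)))
    cbind(s$interactions, site = s$ligand$identifier,
          stringsAsFactors = FALSE)
  }))
}

#' @export
print.nci_profile <- function(x, ...) {
  cat(sprintf("<nci_profile> %s\n",
              if (!is.na(x$header_id)) x$header_id else basename(x$input)))
  cat(sprintf("  %d binding site(s); nucleic-receptor mode: %s\n",
              length(x$sites), x$mode$nucleic_acids_as_receptor))
  sm <- summarize_profile(x, by_chain = FALSE)
  nz <- sm$total[sm$total > 0]
  if (length(nz)) {
    cat("  interactions:",
        paste(sprintf("%s=%d", names(nz), nz), collapse = ", "), "\n")
  } else {
    cat("  no interactions detected\n")
  }
  invisible(x)
}

#' @export
summary.nci_profile <- function(object, ...) {
  sm <- summarize_profile(object)
  structure(list(profile = object, counts = sm), class = "summary.nci_profile")
}

#' @export
print.summary.nci_profile <- function(x, ...) {
  print(x$profile)
  if (length(x$profile$sites)) {
    cat("\nPer-site counts:\n")
    print(x$counts$per_site)
    cat("\nPer-receptor-chain counts:\n")
    print(x$counts$per_chain)
  }
  invisible(x)
}

#' Barplot of interaction counts per type
#'
#' @param x an `nci_profile`
#' @param ... passed to [graphics::barplot()]
#' @export
plot.nci_profile <- function(x, ...) {
  sm <- summarize_profile(x, by_chain = FALSE)
  graphics::barplot(sm$total, las = 2, ylab = "interactions",
                    main = "Detected non-covalent interactions", ...)
  invisible(x)
}
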