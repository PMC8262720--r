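#' @title PDB structure model
#'
#' @description
#' The structure model is a light coordinate/topology container parsed from
#' PDB-format text: an atom table covering every MODEL block, a CONECT
#' adjacency list, and a selected model index. Every downstream stage (ligand
#' extraction, feature perception, interaction detection) sees exactly one
#' model's atoms through [structure_atoms()].
#'
#' Atom table columns: `serial`, `name`, `altloc`, `resname`, `chain`,
#' `resseq`, `icode`, `x`, `y`, `z`, `occ`, `element`, `hetero` (HETATM
#' record), `model`. Blank chain identifiers are normalised to `"_"`.
#' Alternate locations are pruned at parse time: the highest-occupancy altloc
#' per atom name is kept (ties prefer altloc "A", then the first encountered),
#' so all geometry is single-conformer.
#'
#' @name structure-model
NULL

TWO_LETTER_ELEMENTS <- c(
  "FE", "ZN", "MG", "MN", "CU", "NI", "CO", "CD", "CA", "NA", "CL",
  "BR", "SE", "LI", "SR", "CS", "BA", "RB", "AL", "SI", "AS", "MO", "HG"
)

METAL_ELEMENTS_DEFAULT <- c("NA", "K", "MG", "CA", "MN", "FE", "CO", "NI",
                            "CU", "ZN", "CD")

AMINO_ACIDS <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")
DNA_RESIDUES <- c("DT", "DA", "DC", "DG")
RNA_RESIDUES <- c("U", "A", "C", "G")
WATER_RESIDUES <- c("HOH", "WAT", "DOD")

#' Classify a residue name
#'
#' Classification is a pure function of the residue name. Nucleic residues
#' are recognised by exact name: `U`, `A`, `C`, `G` are RNA and `DT`, `DA`,
#' `DC`, `DG` are DNA. Waters are `HOH`, `WAT`, `DOD`. Single-atom residues
#' whose name is a metal element are `metal_ion`; the 20 standard amino-acid
#' codes are `amino_acid`; everything else is `other_hetero`.
#'
#' @param name residue name (3 characters or fewer, case-insensitive)
#' @return one of `"amino_acid"`, `"dna"`, `"rna"`, `"water"`, `"metal_ion"`,
#'   `"other_hetero"` (vectorised)
#' @export
#' @examples
#' residue_kind(c("ALA", "DG", "U", "HOH", "MG", "ATP"))
residue_kind <- function(name) {
  name <- toupper(trimws(name))
  out <- rep("other_hetero", length(name))
  out[name %in% AMINO_ACIDS] <- "amino_acid"
  out[name %in% DNA_RESIDUES] <- "dna"
  out[name %in% RNA_RESIDUES] <- "rna"
  out[name %in% WATER_RESIDUES] <- "water"
  out[name %in% METAL_ELEMENTS_DEFAULT] <- "metal_ion"
  out
}

infer_element <- function(name, resname) {
  # strip digits and primes; PDB hydrogen names may start with a digit
  raw <- trimws(name)
  clean <- toupper(gsub("[0-9']", "", raw))
  if (nchar(clean) == 0) return("X")
  if (grepl("^[0-9]", raw) && substr(clean, 1, 1) == "H") return("H")
  two <- substr(clean, 1, 2)
  resname <- toupper(trimws(resname))
  # two-letter symbols preferred for metals/halogens, but only when the
  # name cannot be a greek-lettered carbon/nitrogen (e.g. "CA" = C-alpha):
  # a residue named like the atom (ions: resname CA, FE, ZN...) decides.
  if (two %in% TWO_LETTER_ELEMENTS) {
    if (resname == two || !(substr(two, 1, 1) %in% c("C", "N", "O", "H")))
      return(paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))))
  }
  substr(clean, 1, 1)
}

norm_element <- function(e) {
  e <- trimws(e)
  paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, 2)))
}

parse_error <- function(msg, line = NA_integer_) {
  stop(structure(
    class = c("nci_parse_error", "error", "condition"),
    list(message = if (is.na(line)) msg else sprintf("%s (line %d)", msg, line),
         call = NULL, line = line)
  ))
}

#' Parse a PDB-format structure
#'
#' Reads ATOM/HETATM records of all MODEL blocks, CONECT records (kept as an
#' adjacency list for ligand bond perception) and the HEADER identifier.
#' TER/END records delimit chains/models. Alternate locations are reduced to
#' a single conformer (highest occupancy, ties to altloc "A"/first seen).
#' Element symbols come from columns 77-78 or are inferred from the atom name
#' when absent.
#'
#' @param source path to a PDB file, or a character vector of PDB lines
#' @return an object of class `nci_structure`
#' @export
#' @examples
#' pdb <- c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
#'          "END")
#' s <- parse_pdb(pdb)
#' structure_atoms(s)
parse_pdb <- function(source) {
  lines <- if (length(source) == 1 && !grepl("\n", source) &&
               file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(source, "\n", fixed = TRUE))
  }
  if (length(lines) == 0 || all(!nzchar(trimws(lines))))
    parse_error("empty input: no PDB records found")

  rec <- substr(lines, 1, 6)
  header_id <- NA_character_
  hline <- which(trimws(rec) == "HEADER")
  if (length(hline)) {
    id <- trimws(substr(lines[hline[1]], 63, 66))
    if (nchar(id) == 4) header_id <- id
  }

  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- trimws(rec) == "MODEL"
  model_no <- cumsum(is_model)
  model_no[model_no == 0] <- 1L
  if (!any(is_atom)) {
    first_bad <- which(nzchar(trimws(lines)))[1]
    parse_error("no parsable ATOM/HETATM coordinate records", first_bad)
  }

  al <- lines[is_atom]
  idx <- which(is_atom)
  num <- function(from, to) suppressWarnings(as.numeric(substr(al, from, to)))
  x <- num(31, 38); y <- num(39, 46); z <- num(47, 54)
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad))
    parse_error("non-numeric coordinates in ATOM/HETATM record", idx[bad[1]])

  occ <- num(55, 60)
  occ[!is.finite(occ)] <- 1.0
  serial <- suppressWarnings(as.integer(substr(al, 7, 11)))
  if (anyNA(serial))
    parse_error("unreadable atom serial", idx[which(is.na(serial))[1]])

  name <- trimws(substr(al, 13, 16))
  altloc <- substr(al, 17, 17)
  altloc[altloc == " "] <- ""
  resname <- toupper(trimws(substr(al, 18, 20)))
  chain <- substr(al, 22, 22)
  chain[chain == " "] <- "_"
  resseq <- suppressWarnings(as.integer(substr(al, 23, 26)))
  resseq[is.na(resseq)] <- 0L
  icode <- substr(al, 27, 27)
  icode[icode == " "] <- ""
  elem_col <- trimws(substr(al, 77, 78))
  hetero <- substr(al, 1, 6) == "HETATM"

  element <- ifelse(nzchar(elem_col), norm_element(elem_col), NA_character_)
  miss <- which(is.na(element))
  if (length(miss)) {
    element[miss] <- norm_element(vapply(
      miss, function(i) infer_element(substr(al[i], 13, 16), resname[i]),
      character(1)))
  }

  atoms <- data.frame(
    serial = serial, name = name, altloc = altloc, resname = resname,
    chain = chain, resseq = resseq, icode = icode,
    x = x, y = y, z = z, occ = occ, element = element, hetero = hetero,
    model = as.integer(model_no[is_atom]),
    stringsAsFactors = FALSE
  )

  # altloc pruning: keep one conformer per (model, residue, atom name)
  if (any(nzchar(atoms$altloc))) {
    key <- paste(atoms$model, atoms$chain, atoms$resseq, atoms$icode,
                 atoms$resname, atoms$name, sep = "\r")
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i) {
      if (length(i) == 1) return(i)
      best <- i[atoms$occ[i] == max(atoms$occ[i])]
      if (length(best) > 1) {
        a <- best[atoms$altloc[best] == "A"]
        best <- if (length(a)) a[1] else best[1]
      }
      best
    }), use.names = FALSE)
    atoms <- atoms[sort(keep), , drop = FALSE]
    rownames(atoms) <- NULL
  }

  # CONECT adjacency (serial pairs, deduplicated, undirected)
  cl <- lines[trimws(rec) == "CONECT"]
  conect <- data.frame(from = integer(0), to = integer(0))
  if (length(cl)) {
    pairs <- do.call(rbind, lapply(cl, function(l) {
      f <- suppressWarnings(as.integer(substr(l, 7, 11)))
      tos <- vapply(c(12, 17, 22, 27), function(p)
        suppressWarnings(as.integer(substr(l, p, p + 4))), integer(1))
      tos <- tos[!is.na(tos)]
      if (is.na(f) || !length(tos)) return(NULL)
      cbind(from = pmin(f, tos), to = pmax(f, tos))
    }))
    if (!is.null(pairs)) {
      conect <- unique(as.data.frame(pairs))
      rownames(conect) <- NULL
    }
  }

  s <- structure(list(
    atoms = atoms,
    conect = conect,
    nmodels = max(atoms$model),
    selected_model = 1L,
    header_id = header_id
  ), class = "nci_structure")
  s
}

#' Select one model of a multi-model structure
#'
#' Indices are 1-based, matching MODEL record numbering. All atom-yielding
#' accessors are restricted to the selected model afterwards; model 1 is the
#' default at parse time.
#'
#' @param s an `nci_structure`
#' @param index model number
#' @return the structure with `selected_model` set
#' @export
select_model <- function(s, index) {
  stopifnot(inherits(s, "nci_structure"))
  index <- as.integer(index)
  if (length(index) != 1 || is.na(index) || index < 1 || index > s$nmodels)
    stop(sprintf("model %s not present; available models: %s",
                 index, paste(seq_len(s$nmodels), collapse = ", ")))
  s$selected_model <- index
  s
}

#' Atoms of the selected model
#'
#' @param s an `nci_structure`
#' @param heavy if TRUE, drop hydrogens
#' @return the atom data frame restricted to the selected model
#' @export
structure_atoms <- function(s, heavy = FALSE) {
  a <- s$atoms[s$atoms$model == s$selected_model, , drop = FALSE]
  if (heavy) a <- a[a$element != "H", , drop = FALSE]
  rownames(a) <- NULL
  a
}

# Residue key: identifies a residue uniquely within one model
res_key <- function(atoms) {
  paste(atoms$chain, atoms$resseq, atoms$icode, atoms$resname, sep = ":")
}

# Human-readable residue label, e.g. "PHE438" / "DG7" (chain carried separately)
res_label <- function(resname, resseq, icode = "") {
  paste0(trimws(resname), resseq, icode)
}

#' Serialise a structure back to PDB text
#'
#' Writes ATOM/HETATM (and MODEL/ENDMDL for multi-model structures) plus the
#' retained CONECT records. Coordinates keep PDB 3-decimal precision.
#'
#' @param s an `nci_structure`
#' @param path optional output file; when NULL the lines are returned
#' @return character vector of PDB lines (invisibly when `path` is given)
#' @export
write_pdb <- function(s, path = NULL) {
  stopifnot(inherits(s, "nci_structure"))
  fmt_atom <- function(a) {
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            ifelse(a$hetero, "HETATM", "ATOM"), a$serial,
            formatC(a$name, width = 4, flag = "-"),
            ifelse(nzchar(a$altloc), a$altloc, " "),
            a$resname, ifelse(a$chain == "_", " ", a$chain),
            a$resseq, ifelse(nzchar(a$icode), a$icode, " "),
            a$x, a$y, a$z, a$occ, 0,
            toupper(a$element))
  }
  out <- character(0)
  multi <- s$nmodels > 1
  for (m in seq_len(s$nmodels)) {
    a <- s$atoms[s$atoms$model == m, , drop = FALSE]
    if (multi) out <- c(out, sprintf("MODEL     %4d", m))
    out <- c(out, fmt_atom(a))
    if (multi) out <- c(out, "ENDMDL")
  }
  if (nrow(s$conect)) {
    out <- c(out, sprintf("CONECT%5d%5d", s$conect$from, s$conect$to))
  }
  out <- c(out, "END")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' @export
print.nci_structure <- function(x, ...) {
  a <- structure_atoms(x)
  kinds <- table(residue_kind(a$resname[!duplicated(res_key(a))]))
  cat(sprintf("<nci_structure> %d model(s), selected %d; %d atoms in selected model\n",
              x$nmodels, x$selected_model, nrow(a)))
  cat("  residues:", paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n")
  if (!is.na(x$header_id)) cat("  header id:", x$header_id, "\n")
  invisible(x)
}
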