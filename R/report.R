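#' @title Reporting
#'
#' @description
#' Serialises per-binding-site results into machine-readable XML and
#' human-readable aligned text with deterministic ordering: binding sites by
#' ligand identifier (chain, then sequence number); interactions by type
#' (fixed catalogue order), then receptor residue, then distance. Distances
#' and angles are fixed at two decimals. The same input always produces
#' byte-identical output.
#'
#' @name reporting
NULL

fmt2 <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.2f", x))

rec_res_label <- function(df, i = seq_len(nrow(df))) {
  res_label(df$rec_resname[i], df$rec_resseq[i], df$rec_icode[i])
}

#' Write the XML report
#'
#' @param p an `nci_profile`
#' @param path optional output file
#' @return an `xml2` document (invisibly when `path` given)
#' @export
write_report_xml <- function(p, path = NULL) {
  doc <- xml2::xml_new_root("interaction_profile",
                            engine = "nciprofiler", version = p$version,
                            input = basename(p$input),
                            header_id = ifelse(is.na(p$header_id), "",
                                               p$header_id),
                            model = as.character(p$structure$selected_model))
  mode_node <- xml2::xml_add_child(doc, "mode",
    nucleic_acids_as_receptor = tolower(p$mode$nucleic_acids_as_receptor),
    intra_chain = tolower(p$mode$intra_chain),
    modified_residues_as_ligand = tolower(p$mode$modified_residues_as_ligand),
    ligand_exclusion_list = paste(p$mode$ligand_exclusion_list,
                                  collapse = ","))
  th <- xml2::xml_add_child(doc, "thresholds")
  for (k in names(p$config))
    xml2::xml_set_attr(th, k, sprintf("%g", p$config[[k]]))

  for (sdat in p$sites) {
    lig <- sdat$ligand
    bs <- xml2::xml_add_child(doc, "bindingsite", id = lig$identifier)
    xml2::xml_add_child(bs, "ligand",
                        identifier = lig$identifier, kind = lig$kind,
                        composite = tolower(lig$composite),
                        residues = as.character(length(lig$residue_keys)))
    rs <- sdat$site$receptor_kind_summary
    xml2::xml_add_child(bs, "receptor",
                        amino_acid = as.character(rs[["amino_acid"]]),
                        dna = as.character(rs[["dna"]]),
                        rna = as.character(rs[["rna"]]),
                        other = as.character(rs[["other"]]),
                        residues = as.character(length(sdat$site$receptor_keys)))
    ints <- xml2::xml_add_child(bs, "interactions")
    inter <- sdat$interactions
    for (i in seq_len(nrow(inter))) {
      at <- list(
        rec_residue = rec_res_label(inter, i),
        rec_chain = inter$rec_chain[i],
        lig_residue = res_label(inter$lig_resname[i], inter$lig_resseq[i],
                                inter$lig_icode[i]),
        lig_chain = inter$lig_chain[i],
        lig_serials = inter$lig_serials[i],
        rec_serials = inter$rec_serials[i],
        dist = fmt2(inter$dist[i]),
        receptor_is_nucleic = tolower(inter$receptor_is_nucleic[i]))
      opt <- c(dist2 = fmt2(inter$dist2[i]), angle = fmt2(inter$angle[i]),
               angle2 = fmt2(inter$angle2[i]), offset = fmt2(inter$offset[i]),
               donor_side = inter$donor_side[i],
               don_serial = as.character(inter$don_serial[i]),
               acc_serial = as.character(inter$acc_serial[i]),
               water_serial = as.character(inter$water_serial[i]),
               geom_label = inter$geom_label[i],
               coord_num = as.character(inter$coord_num[i]))
      opt <- opt[!is.na(opt)]
      if (isTRUE(inter$unverified[i])) opt <- c(opt, unverified = "true")
      do.call(xml2::xml_add_child,
              c(list(ints, inter$type[i]), as.list(c(at, opt))))
    }
  }
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Write the flat-text report
#'
#' Same content as the XML in aligned tables, one section per binding site.
#' Receptor residues are labelled Name+Number (e.g. `PHE438`).
#'
#' @param p an `nci_profile`
#' @param path optional output file
#' @return character vector of lines (invisibly when `path` given)
#' @export
write_report_text <- function(p, path = NULL) {
  out <- c(
    sprintf("nciprofiler %s interaction report", p$version),
    sprintf("input: %s%s", basename(p$input),
            if (!is.na(p$header_id)) sprintf(" (%s)", p$header_id) else ""),
    sprintf("model: %d  nucleic-receptor: %s  intra-chain: %s",
            p$structure$selected_model, p$mode$nucleic_acids_as_receptor,
            p$mode$intra_chain),
    sprintf("thresholds: %s",
            paste(sprintf("%s=%g", names(p$config), unlist(p$config)),
                  collapse = " ")),
    "")
  if (!length(p$sites)) out <- c(out, "no binding sites found")
  for (sdat in p$sites) {
    lig <- sdat$ligand
    out <- c(out, sprintf("== binding site %s (%s) ==", lig$identifier,
                          lig$kind))
    rs <- sdat$site$receptor_kind_summary
    out <- c(out, sprintf("receptor residues: %d (amino_acid=%d dna=%d rna=%d other=%d)",
                          length(sdat$site$receptor_keys), rs[["amino_acid"]],
                          rs[["dna"]], rs[["rna"]], rs[["other"]]))
    inter <- sdat$interactions
    if (!nrow(inter)) {
      out <- c(out, "no interactions detected", "")
      next
    }
    for (tp in INTERACTION_TYPES) {
      sub <- inter[inter$type == tp, , drop = FALSE]
      if (!nrow(sub)) next
      out <- c(out, sprintf("-- %s (%d) --", tp, nrow(sub)))
      hdr <- sprintf("%-10s %-5s %-8s %-8s %-8s %-14s %-14s %s",
                     "RESIDUE", "CHAIN", "DIST", "ANGLE", "OFFSET",
                     "LIG_ATOMS", "REC_ATOMS", "DETAILS")
      rows <- vapply(seq_len(nrow(sub)), function(i) {
        details <- c(
          if (!is.na(sub$geom_label[i])) sub$geom_label[i],
          if (!is.na(sub$donor_side[i]))
            paste0("donor=", sub$donor_side[i]),
          if (!is.na(sub$water_serial[i]))
            paste0("water=", sub$water_serial[i]),
          if (!is.na(sub$dist2[i])) paste0("dist2=", fmt2(sub$dist2[i])),
          if (!is.na(sub$angle2[i])) paste0("angle2=", fmt2(sub$angle2[i])),
          if (!is.na(sub$coord_num[i]))
            paste0("coordination=", sub$coord_num[i]),
          if (isTRUE(sub$unverified[i])) "geometry-unverified")
        sprintf("%-10s %-5s %-8s %-8s %-8s %-14s %-14s %s",
                rec_res_label(sub, i), sub$rec_chain[i],
                ifelse(is.na(sub$dist[i]), "-", fmt2(sub$dist[i])),
                ifelse(is.na(sub$angle[i]), "-", fmt2(sub$angle[i])),
                ifelse(is.na(sub$offset[i]), "-", fmt2(sub$offset[i])),
                sub$lig_serials[i], sub$rec_serials[i],
                paste(details, collapse = " "))
      }, character(1))
      out <- c(out, hdr, rows)
    }
    out <- c(out, "")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Write report files next to an input
#'
#' Produces `<input>.report.xml` and/or `<input>.report.txt` in `out_dir`.
#'
#' @param p an `nci_profile`
#' @param out_dir output directory (created if missing)
#' @param formats subset of `c("xml", "txt")`
#' @return named character vector of written paths
#' @export
write_report <- function(p, out_dir = ".", formats = c("xml", "txt")) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  base <- tools::file_path_sans_ext(basename(p$input))
  if (base %in% c("", "<text>")) base <- "structure"
  paths <- character(0)
  if ("xml" %in% formats) {
    f <- file.path(out_dir, paste0(base, ".report.xml"))
    write_report_xml(p, f)
    paths["xml"] <- f
  }
  if ("txt" %in% formats) {
    f <- file.path(out_dir, paste0(base, ".report.txt"))
    write_report_text(p, f)
    paths["txt"] <- f
  }
  paths
}

#' Parse interaction counts back from a report
#'
#' Round-trip utility: recovers per-type interaction counts from an XML
#' report (or a text report) for consistency checks against the in-memory
#' profile.
#'
#' @param path report file (.xml or .txt)
#' @return named integer vector, one count per interaction type
#' @export
read_report_counts <- function(path) {
  counts <- stats::setNames(integer(length(INTERACTION_TYPES)),
                            INTERACTION_TYPES)
  if (grepl("\\.xml$", path)) {
    doc <- xml2::read_xml(path)
    for (tp in INTERACTION_TYPES)
      counts[tp] <- length(xml2::xml_find_all(
        doc, sprintf("//interactions/%s", tp)))
  } else {
    lines <- readLines(path, warn = FALSE)
    m <- regmatches(lines, regexec("^-- ([a-z]+) \\(([0-9]+)\\) --$", lines))
    for (g in m) if (length(g) == 3 && g[2] %in% INTERACTION_TYPES)
      counts[g[2]] <- counts[g[2]] + as.integer(g[3])
  }
  counts
}

#' Validate an XML report against the shipped schema
#'
#' @param path_or_doc report path or `xml2` document
#' @return TRUE/FALSE with validation errors as an attribute
#' @export
validate_report_xml <- function(path_or_doc) {
  doc <- if (inherits(path_or_doc, "xml_document")) path_or_doc
         else xml2::read_xml(path_or_doc)
  xsd_path <- system.file("extdata", "report.xsd", package = "nciprofiler")
  if (!nzchar(xsd_path)) xsd_path <- file.path("inst", "extdata", "report.xsd")
  xml2::xml_validate(doc, xml2::read_xml(xsd_path))
}
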