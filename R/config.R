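#' Default geometric thresholds
#'
#' Every numeric cutoff used by any detector, user-overridable. Distances are
#' in Angstrom, angles in degrees. All distance/angle thresholds are
#' inclusive: a contact exactly at a `*_max` bound (or exactly at an angle
#' minimum) is reported.
#'
#' \describe{
#'   \item{hydroph_dist_max}{max C...C distance for hydrophobic contacts (4.0)}
#'   \item{hbond_dist_max}{max donor-acceptor heavy-atom distance (4.1)}
#'   \item{hbond_don_angle_min}{min D-H...A angle (100)}
#'   \item{pistack_dist_max}{max ring centroid-centroid distance (5.5)}
#'   \item{pistack_ang_dev}{allowed interplanar deviation from 0 (parallel)
#'     or 90 (T-shape) degrees (30)}
#'   \item{pistack_offset_max}{max lateral centroid offset (2.0)}
#'   \item{pication_dist_max}{max ring-centroid to charge distance (6.0)}
#'   \item{saltbridge_dist_max}{max charged-centroid distance (5.5)}
#'   \item{halogen_dist_max}{max X...acceptor distance (4.0)}
#'   \item{halogen_don_angle, halogen_don_angle_dev}{C-X...A target angle and
#'     tolerance (165 +/- 30)}
#'   \item{halogen_acc_angle, halogen_acc_angle_dev}{Y-A...X target angle and
#'     tolerance (120 +/- 30)}
#'   \item{water_bridge_mindist, water_bridge_maxdist}{polar-atom to water-O
#'     leg bounds (2.5, 4.1)}
#'   \item{water_bridge_omega_min, water_bridge_omega_max}{water-centred
#'     angle window (75, 140)}
#'   \item{metal_dist_max}{max metal-target coordination distance (3.0)}
#'   \item{binding_site_dist}{receptor shell around a ligand (7.5)}
#' }
#'
#' @return named list of class `nci_config`
#' @export
default_config <- function() {
  structure(list(
    hydroph_dist_max = 4.0,
    hbond_dist_max = 4.1,
    hbond_don_angle_min = 100,
    pistack_dist_max = 5.5,
    pistack_ang_dev = 30,
    pistack_offset_max = 2.0,
    pication_dist_max = 6.0,
    saltbridge_dist_max = 5.5,
    halogen_dist_max = 4.0,
    halogen_don_angle = 165,
    halogen_don_angle_dev = 30,
    halogen_acc_angle = 120,
    halogen_acc_angle_dev = 30,
    water_bridge_mindist = 2.5,
    water_bridge_maxdist = 4.1,
    water_bridge_omega_min = 75,
    water_bridge_omega_max = 140,
    metal_dist_max = 3.0,
    binding_site_dist = 7.5
  ), class = "nci_config")
}

config_error <- function(msg) {
  stop(structure(class = c("nci_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Validate a threshold configuration
#'
#' Checks that all thresholds are positive and that paired bounds satisfy
#' min < max. Called by every entry point that accepts a config.
#'
#' @param cfg an `nci_config`
#' @return the config, invisibly, or an error of class `nci_config_error`
#' @export
validate_config <- function(cfg) {
  defaults <- default_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    config_error(sprintf("unknown threshold key(s): %s; valid keys: %s",
                         paste(unknown, collapse = ", "),
                         paste(names(defaults), collapse = ", ")))
  vals <- unlist(cfg)
  if (any(!is.finite(vals)) || any(vals <= 0))
    config_error(sprintf("thresholds must be positive finite numbers; offending: %s",
                         paste(names(vals)[!is.finite(vals) | vals <= 0],
                               collapse = ", ")))
  if (cfg$water_bridge_mindist >= cfg$water_bridge_maxdist)
    config_error("water_bridge_mindist must be < water_bridge_maxdist")
  if (cfg$water_bridge_omega_min >= cfg$water_bridge_omega_max)
    config_error("water_bridge_omega_min must be < water_bridge_omega_max")
  invisible(cfg)
}

#' Override thresholds
#'
#' @param cfg base config (default: [default_config()])
#' @param ... named numeric overrides, e.g. `hbond_dist_max = 3.0`
#' @return validated `nci_config`
#' @export
update_config <- function(cfg = default_config(), ...) {
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)[1]))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    config_error(sprintf("unknown threshold key(s): %s; valid keys: %s",
                         paste(unknown, collapse = ", "),
                         paste(names(cfg), collapse = ", ")))
  for (k in names(over)) cfg[[k]] <- as.numeric(over[[k]])
  validate_config(cfg)
  cfg
}

#' Analysis mode flags
#'
#' @param nucleic_acids_as_receptor treat DNA/RNA residues as receptor
#'   (TRUE) or as ligand entities (FALSE, the default)
#' @param intra_chain report receptor residues on a polymer ligand's own
#'   chain (default TRUE)
#' @param modified_residues_as_ligand treat HETATM residues covalently
#'   linked into a polymer chain as ligand candidates instead of receptor
#' @param ligand_exclusion_list residue names never promoted to ligand
#'   entities (ubiquitous buffer/cryo agents by default)
#' @param halogen_include_fluorine count C-F as a halogen-bond donor
#' @return list of class `nci_mode`
#' @export
analysis_mode <- function(nucleic_acids_as_receptor = FALSE,
                          intra_chain = TRUE,
                          modified_residues_as_ligand = FALSE,
                          ligand_exclusion_list = c("GOL", "EDO", "SO4",
                                                    "PO4", "ACT", "DMS"),
                          halogen_include_fluorine = FALSE) {
  structure(list(
    nucleic_acids_as_receptor = isTRUE(nucleic_acids_as_receptor),
    intra_chain = isTRUE(intra_chain),
    modified_residues_as_ligand = isTRUE(modified_residues_as_ligand),
    ligand_exclusion_list = toupper(ligand_exclusion_list),
    halogen_include_fluorine = isTRUE(halogen_include_fluorine)
  ), class = "nci_mode")
}

#' Load thresholds and mode flags from a flat key = value file
#'
#' Lines are `key = value`; `#` starts a comment. Threshold keys must be
#' known and pass validation; the boolean mode flags
#' (`nucleic_acids_as_receptor`, `intra_chain`, `modified_residues_as_ligand`)
#' and `ligand_exclusion_list` (comma-separated) are also accepted. An empty
#' file yields all defaults.
#'
#' @param path config file path
#' @return list with elements `config` (`nci_config`) and `mode` (`nci_mode`)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) config_error(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- default_config()
  mode_args <- list()
  for (l in lines) {
    if (!grepl("=", l, fixed = TRUE))
      config_error(sprintf("malformed config line (expected key = value): '%s'", l))
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (key %in% names(cfg)) {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) config_error(sprintf("non-numeric value for %s: '%s'", key, val))
      cfg[[key]] <- num
    } else if (key %in% c("nucleic_acids_as_receptor", "intra_chain",
                          "modified_residues_as_ligand",
                          "halogen_include_fluorine")) {
      mode_args[[key]] <- toupper(val) %in% c("TRUE", "YES", "1", "ON")
    } else if (key == "ligand_exclusion_list") {
      mode_args[[key]] <- trimws(strsplit(val, ",")[[1]])
    } else {
      config_error(sprintf("unknown config key: %s; valid keys: %s",
                           key,
                           paste(c(names(cfg), "nucleic_acids_as_receptor",
                                   "intra_chain", "modified_residues_as_ligand",
                                   "halogen_include_fluorine",
                                   "ligand_exclusion_list"), collapse = ", ")))
    }
  }
  validate_config(cfg)
  list(config = cfg, mode = do.call(analysis_mode, mode_args))
}
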