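# Shared fixtures, built once per test run.

fixture_dir <- local({
  d <- NULL
  function() {
    if (is.null(d)) {
      d <<- file.path(tempdir(), "nci-fixtures")
      dir.create(d, showWarnings = FALSE)
    }
    d
  }
})

fixture_path <- function(name) file.path(fixture_dir(), paste0(name, ".pdb"))

# one PDB file + fixture object per standard plant spec (cached on disk)
standard_fixture <- local({
  cache <- list()
  function(name) {
    if (is.null(cache[[name]])) {
      spec <- standard_fixture_specs()[[name]]
      stopifnot(!is.null(spec))
      cache[[name]] <<- generate_fixture(list(spec), fixture_path(name))
    }
    cache[[name]]
  }
})

profile_fixture <- function(name, config = default_config(), ...) {
  fx <- standard_fixture(name)
  mode <- analysis_mode(nucleic_acids_as_receptor = fx$nucleic_mode, ...)
  profile_complex(fx$path, config = config, mode = mode)
}

# minimal PDB text: a single alanine with backbone + CB
ala_pdb_lines <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.986  -0.773  -1.199  1.00  0.00           C",
    "END")
}

# idealised free amino-acid/nucleotide coordinates for template tests:
# a residue assembled from the package's own fixture groups
residue_pdb <- function(resname, atoms_df) {
  s <- structure(list(
    atoms = cbind(atoms_df[, c("name", "altloc", "resname", "chain", "resseq",
                               "icode", "x", "y", "z", "occ", "element",
                               "hetero")],
                  serial = seq_len(nrow(atoms_df)), model = 1L),
    conect = data.frame(from = integer(0), to = integer(0)),
    nmodels = 1L, selected_model = 1L, header_id = NA_character_),
    class = "nci_structure")
  s$atoms <- s$atoms[, c("serial", "name", "altloc", "resname", "chain",
                         "resseq", "icode", "x", "y", "z", "occ", "element",
                         "hetero", "model")]
  s
}
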