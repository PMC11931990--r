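# Compact toy geometry used throughout the screening tests: residue ranges
# small enough that donor-acceptor distances fall in the tens-of-angstrom
# regime where Forster transfer is informative.
toy_acceptor_positions <- c(5, 12, 18, 22, 25, 28)
toy_donor_positions <- c(2, 4, 6, 13, 16, 20, 29)

toy_receptor <- function(...) {
  make_toy_dimer("agp1", site_positions = toy_acceptor_positions,
                 chain_ids = c("A", "B"), n_residues = 30, ...)
}

toy_ligand <- function(...) {
  make_toy_dimer("agp2", site_positions = toy_donor_positions,
                 chain_ids = c("C", "D"), n_residues = 30, ...)
}

toy_scheme <- function(...) {
  labeling_scheme(donor_positions = toy_donor_positions,
                  acceptor_positions = toy_acceptor_positions, ...)
}

# A two-residue, two-chain hand-written PDB fixture with exact coordinates.
minimal_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       1.000   2.000   4.500  1.00  0.00           C",
    "ATOM      3  CA  GLY B   1       4.000   6.000   3.000  1.00  0.00           C",
    "END"), path)
  path
}

# Structure model built directly from an atom table (no file round trip).
atoms_model <- function(df, id = "m") structure_model(df, model_id = id)
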