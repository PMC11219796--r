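# Shared fixtures: tiny grids, models and ensembles built in code.

rand_grid <- function(d = c(8, 8, 8), voxel = 1.5, origin = c(0, 0, 0),
                      seed = 1) {
  set.seed(seed)
  voxel_grid(array(rnorm(prod(d)), dim = d), voxel, origin)
}

# a hand-written three-residue peptide backbone fragment (N, CA, C per
# residue), with a hydrogen and a water that the reader must drop
PDB_3RES <- c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
  "ATOM      4  H   ALA A   1       0.500   0.800   0.000  1.00  0.00           H",
  "ATOM      5  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
  "ATOM      6  CA  GLY A   2       4.000   2.800   0.000  1.00  0.00           C",
  "ATOM      7  C   GLY A   2       5.500   2.700   0.000  1.00  0.00           C",
  "ATOM      8  N   SER A   3       6.200   3.800   0.000  1.00  0.00           N",
  "ATOM      9  CA  SER A   3       7.650   3.850   0.000  1.00  0.00           C",
  "ATOM     10  C   SER A   3       8.200   5.250   0.000  1.00  0.00           C",
  "HETATM   11  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
  "END")

write_pdb_fixture <- function(lines = PDB_3RES) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

# small atomic model at given coordinates (carbon pseudo-atoms)
toy_model <- function(coords, resno = seq_len(nrow(coords)), chain = "A") {
  atomic_model(data.frame(
    element = "C", mass = 12.011,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    resno = resno, chain = chain, stringsAsFactors = FALSE))
}

# random rmsf_map on a grid with a given number of labelled voxels
random_rmsf_map <- function(d = c(23, 17, 19), n_masked = 40, seed = 1) {
  set.seed(seed)
  vals <- array(0, dim = d)
  mask <- array(FALSE, dim = d)
  pick <- sample(prod(d), n_masked)
  vals[pick] <- runif(n_masked, 0.2, 3)
  mask[pick] <- TRUE
  rmsf_map(voxel_grid(vals, 1.5), mask)
}

# deterministic rotation matrix from axis-angle
rotation_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# small fast synthetic spec for module tests (defaults overridable)
small_spec <- function(...) {
  args <- modifyList(list(n_atoms = 60L, n_frames = 80L, margin = 6L),
                     list(...))
  do.call(synthetic_spec, args)
}

# a tiny trained-flag network for plumbing tests
tiny_rmsf_net <- function(variant = "dual", base = 2L, seed = 1L) {
  build_rmsf_network(network_config(variant, base_channels = base, seed = seed))
}
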