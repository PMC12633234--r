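# shared helpers: built in code at test time, no stored fixtures

ncc <- function(a, b) {
  a <- as.vector(a) - mean(a)
  b <- as.vector(b) - mean(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# compact, well-resolved Gaussian phantom: sigma = 4 A at 1 A voxels,
# centers within ~4 A of the origin of a 64-box (band-limit condition holds)
compact_phantom <- function(n_atoms = 10, seed = 1, variance = 16, spread = 4) {
  centers <- cryosim:::with_seed(seed,
    matrix(stats::rnorm(3 * n_atoms, sd = spread), n_atoms, 3))
  gaussian_mixture_volume(centers, 1, variance)
}

# locate the first zero of a radial CTF by coarse sign-change scan plus
# bisection, probing the package CTF along the qy = 0 axis of tiny grids
ctf_first_zero <- function(params, chi_fn, q_hi = 0.2) {
  f <- function(qm) {
    qg <- frequency_grid_2d(c(2, 4), 1 / (4 * qm))
    evaluate_ctf(qg, params, chi_fn = chi_fn)[2, 4]
  }
  qs <- seq(1e-3, q_hi, length.out = 400)
  vals <- vapply(qs, f, numeric(1))
  i <- which(diff(sign(vals)) != 0)[1]
  stats::uniroot(f, c(qs[i], qs[i + 1]), tol = 1e-10)$root
}

# a tiny hand-written PDB with three atoms (one CA)
write_tiny_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.500   3.500   4.500  1.00  0.00           C",
    "ATOM      3  O   ALA A   1       4.000   5.000   6.000  1.00  0.00           O",
    "END"), path)
  path
}

# same three atoms as minimal mmCIF
write_tiny_cif <- function(path) {
  writeLines(c(
    "data_tiny",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N  N  . ALA A 1 1 ? 1.000 2.000 3.000 1.00 0.00 1 ALA A N  1",
    "ATOM 2 C  CA . ALA A 1 1 ? 2.500 3.500 4.500 1.00 0.00 1 ALA A CA 1",
    "ATOM 3 O  O  . ALA A 1 1 ? 4.000 5.000 6.000 1.00 0.00 1 ALA A O  1"),
    path)
  path
}
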