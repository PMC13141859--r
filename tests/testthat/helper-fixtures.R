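# shared fixtures, all generated in code

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_structure <- function(n = 20, scale = 10) {
  atom_tbl(tibble::tibble(
    element = sample(c("C", "N", "O"), n, replace = TRUE),
    name = paste0("X", seq_len(n)),
    residue_index = seq_len(n), residue_name = "ALA", chain = "A",
    x = runif(n, 0, scale), y = runif(n, 0, scale), z = runif(n, 0, scale)))
}

# a hand-written one-residue PDB (N, CA, C) used by the parser tests
toy_pdb_lines <- function() {
  c("ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       3.700   3.000   3.000  1.00  0.00           C",
    "END")
}

write_toy_pdb <- function(lines = toy_pdb_lines()) {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# a two-residue chain with full backbone, for selection tests
two_residue_structure <- function() {
  rows <- expand.grid(name = c("N", "CA", "C", "O"), res = 1:2)
  atom_tbl(tibble::tibble(
    element = c("N", "C", "C", "O")[match(rows$name, c("N", "CA", "C", "O"))],
    name = as.character(rows$name),
    residue_index = rows$res, residue_name = "GLY", chain = "A",
    x = seq_len(8) * 4, y = 0, z = 0))
}

# synthetic trajectory: frames are rigid motions of a base structure plus
# per-frame displacement of the "measured" chain; frame `medoid` stays
# closest to the ensemble centre
jittered_trajectory <- function(n_frames, n_atoms = 12, seed = 1) {
  withr::with_seed(seed, {
    base <- atom_tbl(tibble::tibble(
      element = "C",
      name = rep(c("N", "CA", "C", "O"), length.out = n_atoms),
      residue_index = rep(seq_len(ceiling(n_atoms / 4)), each = 4)[1:n_atoms],
      residue_name = "ALA",
      chain = rep(c("A", "B"), each = n_atoms / 2),
      x = runif(n_atoms, 0, 15), y = runif(n_atoms, 0, 15),
      z = runif(n_atoms, 0, 15)))
    meas <- which(base$chain == "A")
    frames <- lapply(seq_len(n_frames), function(i) {
      xyz <- coords(base)
      xyz[meas, ] <- xyz[meas, ] + matrix(rnorm(length(meas) * 3, sd = 1),
                                          ncol = 3)
      f <- base
      f$x <- xyz[, 1]; f$y <- xyz[, 2]; f$z <- xyz[, 3]
      # global rigid motion so alignment is actually needed
      apply_transform(f, rigid_transform(random_rotation(), rnorm(3, sd = 5)))
    })
    trajectory(frames, seq_len(n_frames))
  })
}
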