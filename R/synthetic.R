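# Synthetic inputs with known ground truth. Every generator is a pure
# function of its seed and parameters, so scenes regenerate bitwise and
# planted truths can be asserted by the downstream pipeline.

hexagon_ring <- function(center, u, v, radius = 1.4, prefix = "C") {
  ang <- (0:5) * pi / 3
  xyz <- t(vapply(ang, function(a) {
    center + radius * (cos(a) * u + sin(a) * v)
  }, numeric(3)))
  tibble(element = "C", name = paste0(prefix, 1:6),
         residue_index = 1L, residue_name = "LIG", chain = "L",
         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], is_het = TRUE)
}

#' Toy diyne PROTAC
#'
#' A minimal rigid-linker PROTAC model: four collinear sp carbons with
#' alternating triple/single bond lengths 1.21 / 1.37 / 1.21 angstrom
#' along z, capped at each end by a rigid planar 6-carbon ring standing
#' in for a warhead. The rings sit off the linker axis so rotation
#' about the diyne is geometrically meaningful. The geometry is
#' deterministic; `seed` is accepted for interface symmetry with the
#' other generators.
#'
#' @param seed unused placeholder (the geometry is fixed).
#' @return a [diyne_ligand]: atoms 1-6 fixed warhead (F1-F6), 7-10
#'   linker (L1-L4), 11-16 mobile warhead (M1-M6).
#' @export
make_toy_ligand <- function(seed = 1) {
  linker_z <- c(0, 1.21, 1.21 + 1.37, 1.21 + 1.37 + 1.21)
  linker <- tibble(element = "C", name = paste0("L", 1:4),
                   residue_index = 1L, residue_name = "LIG", chain = "L",
                   x = 0, y = 0, z = linker_z, is_het = TRUE)
  fixed <- hexagon_ring(center = c(1.6, 0, -1.6),
                        u = c(1, 0, 0), v = c(0, 0, 1), prefix = "F")
  mobile <- hexagon_ring(center = c(1.6, 0, 3.79 + 1.6),
                         u = c(1, 0, 0), v = c(0, 0, 1), prefix = "M")
  atoms <- atom_tbl(dplyr::bind_rows(fixed, linker, mobile),
                    label = "toy diyne PROTAC", source = "make_toy_ligand")
  diyne_ligand(atoms, warhead_fixed = 1:6, warhead_mobile = 11:16,
               linker = 7:10)
}

#' Toy globular protein
#'
#' Residues on a self-avoiding random walk: each residue is a rigid
#' local cluster (backbone N, CA, C, O plus pseudo-sidechain atoms) in
#' a randomly oriented frame. Within-residue and between-residue atom
#' spacings stay at or above 2.6 angstrom, so a toy protein never
#' clashes with itself at the 2.4 angstrom cutoff. Deterministic under
#' `seed`.
#'
#' @param n_residues number of residues (>= 1).
#' @param sidechain_atoms pseudo-sidechain heavy atoms per residue
#'   (0-3).
#' @param radius sphere radius (angstrom) confining the walk.
#' @param seed integer seed.
#' @param chain chain identifier.
#' @return an `atom_tbl` with `n_residues * (4 + sidechain_atoms)`
#'   atoms.
#' @export
make_toy_protein <- function(n_residues, sidechain_atoms = 2, radius = 30,
                             seed = 1, chain = "A") {
  if (n_residues < 1) abort("n_residues must be >= 1")
  if (sidechain_atoms < 0 || sidechain_atoms > 3) {
    abort("sidechain_atoms must be between 0 and 3")
  }
  step <- 8
  withr::with_seed(seed, {
    centers <- matrix(0, n_residues, 3)
    for (i in seq_len(n_residues)[-1]) {
      placed <- FALSE
      for (try in 1:200) {
        dir <- stats::rnorm(3)
        cand <- centers[i - 1, ] + step * dir / sqrt(sum(dir^2))
        far <- all(sqrt(rowSums(sweep(centers[seq_len(i - 1), , drop = FALSE],
                                      2, cand, "-")^2)) >= step - 1e-9)
        if (far && sqrt(sum(cand^2)) <= radius) {
          centers[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(sprintf(
          "could not pack %d residues inside radius %g (failed at residue %d)",
          n_residues, radius, i))
      }
    }
    rows <- lapply(seq_len(n_residues), function(i) {
      # random orthonormal local frame
      q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
      if (det(q) < 0) q[, 1] <- -q[, 1]
      off <- rbind(N = 2.6 * q[, 1], CA = c(0, 0, 0), C = -2.6 * q[, 1],
                   O = 2.6 * q[, 2])
      sc <- rbind(-2.6 * q[, 2], 2.6 * q[, 3], -2.6 * q[, 3])
      if (sidechain_atoms > 0) {
        sc <- sc[seq_len(sidechain_atoms), , drop = FALSE]
        rownames(sc) <- paste0("SC", seq_len(sidechain_atoms))
        off <- rbind(off, sc)
      }
      xyz <- sweep(off, 2, centers[i, ], "+")
      tibble(element = c("N", "C", "C", "O",
                         rep("C", sidechain_atoms)),
             name = rownames(off),
             residue_index = i, residue_name = "ALA", chain = chain,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], is_het = FALSE)
    })
    atom_tbl(dplyr::bind_rows(rows),
             label = sprintf("toy protein (%d residues, seed %d)",
                             n_residues, seed),
             source = "make_toy_protein")
  })
}

#' Plant a ternary screening scene with known viable angles
#'
#' Constructs a toy ligand and two protein-ligand "complexes" placed so
#' that the set of clash-free dihedral grid angles is known exactly by
#' construction: complex A carries a static ring of backbone blocker
#' atoms at every non-designated grid angle on a circle about the
#' linker axis, and complex B carries a single backbone probe atom that
#' sweeps that circle as its warhead alignment rotates with the
#' conformer. At a non-designated angle the probe lands on a blocker
#' (backbone clash); at a designated angle the nearest blocker is a
#' full grid step away (3.5 angstrom at the 10 degree grid, clear of
#' the 2.4 angstrom cutoff). The truth is verified before returning,
#' twice: by an independent brute-force distance check on directly
#' rotated coordinates, and by running the real alignment + screening
#' pipeline; a scene that fails either check is never returned.
#'
#' @param viable_angles subset of the grid angles that must come out
#'   viable.
#' @param seed integer seed (protein body geometry).
#' @param step_deg grid spacing, degrees.
#' @return list of class `planted_scene`: `ligand`, `complex_a`,
#'   `complex_b`, `map_a`, `map_b`, `truth_viable_angles`, `seed`,
#'   `step_deg`.
#' @export
plant_ternary_scene <- function(viable_angles = c(0, 10, 20, 30), seed = 1,
                                step_deg = 10) {
  grid <- seq(0, 360 - step_deg, by = step_deg)
  if (!all(viable_angles %in% grid)) {
    abort("viable_angles must lie on the dihedral grid")
  }
  blocked <- setdiff(grid, viable_angles)
  ligand <- make_toy_ligand()
  ring_r <- 20
  ring_z <- 20

  body_a <- make_toy_protein(5, 2, radius = 12, seed = seed, chain = "A")
  body_a <- apply_transform(body_a, rigid_transform(diag(3), c(0, 0, 60)))
  blockers <- if (length(blocked) > 0) {
    phi <- blocked * pi / 180
    tibble(element = "C", name = "CA",
           residue_index = 1000L + seq_along(blocked), residue_name = "ALA",
           chain = "X",
           x = ring_r * cos(phi), y = ring_r * sin(phi), z = ring_z,
           is_het = FALSE)
  } else {
    NULL
  }
  base_cols <- function(df) {
    as_tibble(df)[c("element", "name", "residue_index", "residue_name",
                    "chain", "x", "y", "z", "is_het")]
  }
  lig_a <- base_cols(ligand$atoms[ligand$warhead_fixed, ])
  complex_a <- atom_tbl(dplyr::bind_rows(base_cols(body_a), blockers, lig_a),
                        label = "planted complex A (target side)",
                        source = "plant_ternary_scene")

  body_b <- make_toy_protein(5, 2, radius = 12, seed = seed + 1, chain = "B")
  body_b <- apply_transform(body_b, rigid_transform(diag(3), c(0, 0, -60)))
  probe <- tibble(element = "C", name = "CA", residue_index = 2000L,
                  residue_name = "ALA", chain = "X",
                  x = ring_r, y = 0, z = ring_z, is_het = FALSE)
  lig_b <- base_cols(ligand$atoms[ligand$warhead_mobile, ])
  complex_b <- atom_tbl(dplyr::bind_rows(base_cols(body_b), probe, lig_b),
                        label = "planted complex B (E3 side)",
                        source = "plant_ternary_scene")

  map_a <- atom_map(paste0("F", 1:6), paste0("F", 1:6))
  map_b <- atom_map(paste0("M", 1:6), paste0("M", 1:6))

  scene <- structure(list(ligand = ligand, complex_a = complex_a,
                          complex_b = complex_b, map_a = map_a,
                          map_b = map_b,
                          truth_viable_angles = sort(viable_angles),
                          seed = seed, step_deg = step_deg),
                     class = "planted_scene")
  verify_planted_scene(scene, grid)
  scene
}

# brute-force verification (direct rotation + all-pairs distances), then
# the real pipeline; both must reproduce the designated set exactly
verify_planted_scene <- function(scene, grid) {
  ligand <- scene$ligand
  a_prot <- select_atoms(scene$complex_a, !.data$is_het, .data$is_heavy)
  b_prot <- select_atoms(scene$complex_b, !.data$is_het, .data$is_heavy)
  xa <- coords(a_prot)
  brute <- vapply(grid, function(ang) {
    xb <- rotate_about_axis(coords(b_prot), ligand$axis_point,
                            ligand$axis_dir, ang)
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
    hit <- d2 < 2.4^2
    bb <- sum(hit & outer(a_prot$is_backbone, b_prot$is_backbone, "&"))
    bb == 0 && sum(hit) <= 20
  }, logical(1))
  if (!setequal(grid[brute], scene$truth_viable_angles)) {
    abort("planted scene failed brute-force verification")
  }
  screen <- screen_conformers(enumerate_conformers(ligand, scene$step_deg),
                              scene$complex_a, scene$map_a,
                              scene$complex_b, scene$map_b)
  if (!setequal(screen$angle[screen$viable], scene$truth_viable_angles)) {
    abort("planted scene failed pipeline verification")
  }
  invisible(scene)
}

#' @export
print.planted_scene <- function(x, ...) {
  cat(sprintf("<planted_scene> seed %d, %d viable of %d grid angles\n",
              x$seed, length(x$truth_viable_angles), 360 / x$step_deg))
  invisible(x)
}

#' Export a planted scene to a directory
#'
#' Writes `complex_a.pdb`, `complex_b.pdb`, `ligand.pdb`, `map_a.txt`,
#' `map_b.txt`, and `truth.json` (viable angles, seed, grid, ligand
#' atom partition by name).
#'
#' @param scene a `planted_scene`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
export_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pdb(scene$complex_a, file.path(dir, "complex_a.pdb"))
  write_pdb(scene$complex_b, file.path(dir, "complex_b.pdb"))
  write_pdb(scene$ligand$atoms, file.path(dir, "ligand.pdb"))
  write_atom_map(scene$map_a, file.path(dir, "map_a.txt"))
  write_atom_map(scene$map_b, file.path(dir, "map_b.txt"))
  jsonlite::write_json(
    list(truth_viable_angles = scene$truth_viable_angles,
         seed = scene$seed, step_deg = scene$step_deg,
         warhead_fixed = scene$ligand$atoms$name[scene$ligand$warhead_fixed],
         warhead_mobile = scene$ligand$atoms$name[scene$ligand$warhead_mobile],
         linker = scene$ligand$atoms$name[scene$ligand$linker]),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate a multi-cycle sensorgram dataset with known truth
#'
#' One sensorgram per concentration of the injection series, each with
#' i.i.d. Gaussian noise drawn from a per-cycle seed derived from
#' `seed`, stacked into the tidy layout [fit_kinetics] consumes. The
#' generating parameters travel with the data in the `truth` attribute
#' for recovery tests.
#'
#' @param truth a [kinetic_params] row.
#' @param series an [injection_series].
#' @param noise_sd Gaussian noise sd, RU.
#' @param seed integer seed.
#' @param dt sampling interval, s.
#' @return tibble (`time`, `response`, `concentration`, `cycle`,
#'   `phase`) with attributes `truth` and `contact_time`.
#' @export
make_sensorgram_dataset <- function(truth, series, noise_sd = 0, seed = 1,
                                    dt = 1) {
  cycles <- lapply(seq_along(series$concentrations), function(i) {
    sg <- simulate_sensorgram(truth, series$concentrations[i],
                              contact_time = series$contact_time,
                              dissociation_time = series$dissociation_time,
                              dt = dt, noise_sd = noise_sd,
                              seed = if (noise_sd > 0) seed * 1000L + i
                                     else NULL)
    sg$cycle <- i
    as_tibble(sg)
  })
  out <- dplyr::bind_rows(cycles)
  attr(out, "truth") <- truth
  attr(out, "contact_time") <- series$contact_time
  out
}
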