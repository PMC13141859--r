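test_that("the restraint schedule has 4 stages releasing monotonically", {
  sched <- build_restraint_schedule()
  expect_equal(nrow(sched), 4)
  expect_true(all(sched$force_constant == 10))
  expect_true(all(sched$action == "minimize"))

  s <- plant_ternary_scene(seed = 5)$complex_a
  sizes <- vapply(sched$restrained,
                  function(r) length(restrained_indices(s, r)), numeric(1))
  expect_true(all(diff(sizes) <= 0))       # each stage only releases atoms
  expect_equal(unname(sizes[4]), 0)        # final stage fully unrestrained
  # released sets are nested, never re-restrained
  sets <- lapply(sched$restrained, restrained_indices, structure = s)
  for (i in 2:4) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("equilibration_filter keeps frames after the discard window", {
  frames <- rep(list(two_residue_structure()), 100)
  traj <- trajectory(frames, seq(0.5, 50, by = 0.5))
  kept <- equilibration_filter(traj, 10)
  expect_equal(length(kept), 80)           # (50 - 10) / 0.5 frames survive
  expect_true(all(kept$times_ns > 10))
  expect_equal(equilibration_filter(traj, 0)$times_ns, traj$times_ns)
  # idempotence
  expect_equal(equilibration_filter(kept, 10)$times_ns, kept$times_ns)
  single <- trajectory(frames[1], 5)
  expect_warning(out <- equilibration_filter(single, 10), "equilibration")
  expect_equal(length(out), 0)
})

test_that("trajectory construction validates times and rosters", {
  f <- two_residue_structure()
  expect_error(trajectory(list(f, f), c(2, 1)), "strictly increasing")
  g <- select_atoms(f, name != "O")
  expect_error(trajectory(list(f, g), 1:2), "roster")
})

test_that("representative selection matches an exhaustive oracle", {
  # independent oracle: brute-force all-pairs median RMSD using bio3d's
  # fitter rather than the package's kabsch path
  oracle_medoid <- function(traj, align_sel, rmsd_sel) {
    roster <- traj$frames[[1]]
    ai <- which(protacscreen:::selection_mask(roster, align_sel))
    ri <- which(protacscreen:::selection_mask(roster, rmsd_sel))
    n <- length(traj$frames)
    med <- numeric(n)
    for (i in seq_len(n)) {
      vals <- c()
      fixed <- as.numeric(t(coords(traj$frames[[i]])))
      for (j in setdiff(seq_len(n), i)) {
        mob <- as.numeric(t(coords(traj$frames[[j]])))
        idx3 <- function(ix) as.numeric(rbind(3 * ix - 2, 3 * ix - 1, 3 * ix))
        moved <- bio3d::fit.xyz(fixed, mob, fixed.inds = idx3(ai),
                                mobile.inds = idx3(ai))
        vals <- c(vals, bio3d::rmsd(fixed, moved, a.inds = idx3(ri),
                                    b.inds = idx3(ri)))
      }
      med[i] <- stats::median(vals)
    }
    which.min(med)
  }
  for (n in c(5, 9, 20)) {
    traj <- jittered_trajectory(n, seed = n)
    got <- select_representative(traj, "backbone chain=B", "calpha chain=A")
    expect_equal(got$index,
                 oracle_medoid(traj, "backbone chain=B", "calpha chain=A"))
  }
})

test_that("representative selection handles edge cases and reordering", {
  f <- jittered_trajectory(1)$frames[[1]]
  single <- trajectory(list(f), 1)
  got <- select_representative(single, "backbone", "calpha")
  expect_equal(got$index, 1)
  expect_equal(got$median_rmsd, 0)     # median over the empty set is 0

  same <- trajectory(rep(list(f), 4), 1:4)
  expect_equal(select_representative(same, "backbone", "calpha")$index, 1)

  traj <- jittered_trajectory(7, seed = 2)
  base <- select_representative(traj, "backbone chain=B", "calpha chain=A")
  perm <- c(4, 1, 7, 2, 6, 3, 5)
  shuffled <- trajectory(traj$frames[perm], 1:7)
  got <- select_representative(shuffled, "backbone chain=B", "calpha chain=A")
  expect_equal(perm[got$index], base$index)   # same frame identity
  expect_error(select_representative(traj, "backbone", "resname=ZZZ"),
               "empty")
})

test_that("trajectories round-trip through multi-model PDB with times", {
  traj <- jittered_trajectory(4, seed = 6)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(trajectory(traj$frames, c(2.5, 5, 7.5, 10)), path)
  back <- read_trajectory_pdb(path)
  expect_equal(length(back), 4)
  expect_equal(back$times_ns, c(2.5, 5, 7.5, 10))
  expect_equal(coords(back$frames[[3]]), coords(traj$frames[[3]]),
               tolerance = 1e-3)
})

test_that("the toy minimizer separates clashes and respects restraints", {
  two <- atom_tbl(tibble::tibble(
    element = "C", name = c("SC1", "SC2"), residue_index = 1:2,
    residue_name = "ALA", chain = "A",
    x = c(0, 0.8), y = 0, z = 0))
  stage_free <- list(restrained = "none", force_constant = 10)
  out <- restrained_minimize(two, two, stage_free, max_steps = 300)
  d_final <- dist(coords(out))[1]
  expect_gt(d_final, 0.8)                       # repulsion pushed them apart
  trace <- attr(out, "energy_trace")
  expect_true(all(diff(trace) <= 1e-12))        # energy never increases

  # a fully restrained displaced atom returns to its reference
  one <- atom_tbl(tibble::tibble(
    element = "C", name = "CA", residue_index = 1, residue_name = "ALA",
    chain = "A", x = 1, y = 0, z = 0))
  ref <- one; ref$x <- 0
  stage_all <- list(restrained = "all_heavy", force_constant = 10)
  back <- restrained_minimize(one, ref, stage_all, max_steps = 500,
                              tol = 1e-6)
  expect_lt(abs(back$x), 0.01)

  # restrained atom moves strictly less than its unrestrained clash partner
  pairx <- atom_tbl(tibble::tibble(
    element = "C", name = c("CA", "SC1"), residue_index = 1:2,
    residue_name = "ALA", chain = "A",
    x = c(0, 1.2), y = 0, z = 0, is_het = c(TRUE, FALSE)))
  stage_lig <- list(restrained = "ligand_only", force_constant = 10)
  relaxed <- restrained_minimize(pairx, pairx, stage_lig, max_steps = 300)
  moved <- abs(coords(relaxed) - coords(pairx))
  expect_lt(sum(moved[1, ]), sum(moved[2, ]))
  expect_error(restrained_minimize(pairx, one, stage_lig), "roster")
})

test_that("the schedule exports as a readable text report", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_restraint_schedule(build_restraint_schedule(), path)
  lines <- readLines(path)
  expect_length(grep("^stage", lines), 4)
  expect_true(any(grepl("force_constant=10", lines)))
})
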