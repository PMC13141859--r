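test_that("kabsch recovers identity, translation, and planted rotations", {
  withr::local_seed(11)
  ref <- matrix(runif(30, 0, 10), ncol = 3)
  same <- kabsch(ref, ref)
  expect_equal(same$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(same$rmsd, 0, tolerance = 1e-9)

  shifted <- sweep(ref, 2, c(5, 0, 0), "+")
  fit <- kabsch(shifted, ref)
  expect_equal(fit$transform$translation, c(-5, 0, 0), tolerance = 1e-9)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)

  for (i in 1:10) {
    r0 <- random_rotation()
    mobile <- ref %*% t(r0)
    fit <- kabsch(mobile, ref)
    expect_equal(fit$transform$rotation, t(r0), tolerance = 1e-6)
    expect_lt(fit$rmsd, 1e-6)
  }
})

test_that("kabsch rejects degenerate input and never returns a mirror", {
  expect_error(kabsch(matrix(1:6, 2), matrix(1:6, 2)), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch(line + 0, line), "collinear")
  # mirrored cloud: best proper fit must still have det +1
  withr::local_seed(4)
  ref <- matrix(rnorm(30), ncol = 3)
  mirrored <- ref %*% diag(c(-1, 1, 1))
  fit <- kabsch(mirrored, ref)
  expect_equal(det(fit$transform$rotation), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd, 0)
})

test_that("kabsch rmsd beats 100 random rigid transforms", {
  withr::local_seed(7)
  mobile <- matrix(runif(36, 0, 10), ncol = 3)
  reference <- mobile %*% t(random_rotation()) +
    matrix(rnorm(36, sd = 0.3), ncol = 3)
  best <- kabsch(mobile, reference)$rmsd
  for (i in 1:100) {
    tf <- rigid_transform(random_rotation(), rnorm(3, sd = 3))
    moved <- sweep(mobile %*% t(tf$rotation), 2, tf$translation, "+")
    expect_gte(rmsd(moved, reference) + 1e-12, best)
  }
})

test_that("kabsch rmsd is invariant to a common rigid motion", {
  withr::local_seed(9)
  a <- matrix(runif(24, 0, 8), ncol = 3)
  b <- a + matrix(rnorm(24, sd = 0.5), ncol = 3)
  base <- kabsch(a, b)$rmsd
  for (i in 1:5) {
    tf <- rigid_transform(random_rotation(), rnorm(3, sd = 10))
    a2 <- sweep(a %*% t(tf$rotation), 2, tf$translation, "+")
    b2 <- sweep(b %*% t(tf$rotation), 2, tf$translation, "+")
    expect_equal(kabsch(a2, b2)$rmsd, base, tolerance = 1e-9)
  }
})

test_that("kabsch agrees with the bio3d least-squares fit", {
  withr::local_seed(21)
  mobile <- matrix(runif(45, 0, 12), ncol = 3)
  reference <- mobile %*% t(random_rotation()) + rnorm(45, sd = 0.4)
  fit <- kabsch(mobile, reference)
  moved <- sweep(mobile %*% t(fit$transform$rotation), 2,
                 fit$transform$translation, "+")
  inds <- seq_len(3 * nrow(mobile))
  oracle <- matrix(suppressWarnings(
    bio3d::fit.xyz(as.numeric(t(reference)), as.numeric(t(mobile)),
                   fixed.inds = inds, mobile.inds = inds)),
    ncol = 3, byrow = TRUE)
  expect_equal(rmsd(moved, reference), rmsd(oracle, reference),
               tolerance = 1e-6)
})

test_that("rmsd matches closed forms and a direct-summation oracle", {
  a <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(rmsd(a, a), 0)
  b <- rbind(c(0, 0, 1), c(1, 0, 0))  # one point off by 1 A
  expect_equal(rmsd(a, b), sqrt(0.5))
  withr::local_seed(3)
  x <- matrix(rnorm(60), ncol = 3)
  y <- matrix(rnorm(60), ncol = 3)
  acc <- 0
  for (i in seq_len(nrow(x))) {
    for (k in 1:3) acc <- acc + (x[i, k] - y[i, k])^2
  }
  expect_equal(rmsd(x, y), sqrt(acc / nrow(x)), tolerance = 1e-12)
  expect_error(rmsd(x, y[1:3, ]), "equal length")
})

test_that("align_partner poses a whole complex from its mapped ligand", {
  scene <- plant_ternary_scene(viable_angles = seq(0, 350, 10), seed = 3)
  conf0 <- enumerate_conformers(scene$ligand, 10)$conformers[[1]]
  # ligand already coincides with the warhead: pose is the identity
  posed <- align_partner(scene$complex_b, scene$map_b, conf0)
  expect_equal(coords(posed), coords(scene$complex_b), tolerance = 1e-8)
  expect_lt(attr(posed, "mapped_rmsd"), 1e-8)

  # rotate the complex 90 degrees about z: the pose must undo it exactly
  tf <- rigid_transform(matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3),
                        c(0, 0, 0))
  displaced <- apply_transform(scene$complex_b, tf)
  reposed <- align_partner(displaced, scene$map_b, conf0)
  expect_equal(coords(reposed), coords(scene$complex_b), tolerance = 1e-6)
  # internal geometry preserved through the pose
  expect_equal(as.matrix(dist(coords(reposed))),
               as.matrix(dist(coords(displaced))), tolerance = 1e-8)

  expect_error(align_partner(scene$complex_b,
                             atom_map(c("M1", "M2"), c("M1", "M2")), conf0),
               "at least 3")
  expect_error(align_partner(scene$complex_b,
                             atom_map("QQ1", "M1"), conf0),
               "not found")
})

test_that("atom maps round-trip through their text format", {
  map <- atom_map(paste0("C", 1:4), paste0("W", 1:4))
  path <- withr::local_tempfile(fileext = ".txt")
  write_atom_map(map, path)
  expect_equal(as.data.frame(read_atom_map(path)), as.data.frame(map))
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("A B", "C"), bad)
  expect_error(read_atom_map(bad), "line 2")
  expect_error(atom_map(c("A", "A"), c("B", "C")), "unique")
})
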