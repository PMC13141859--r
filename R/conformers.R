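#' Rotate points about an axis (Rodrigues rotation)
#'
#' @param points n x 3 matrix (or length-3 vector) of coordinates.
#' @param axis_point a point on the rotation axis.
#' @param axis_dir axis direction; must have non-zero length (it is
#'   normalised internally).
#' @param angle_deg rotation angle in degrees (right-handed about
#'   `axis_dir`).
#' @return rotated coordinates, same shape as `points`.
#' @export
rotate_about_axis <- function(points, axis_point, axis_dir, angle_deg) {
  was_vec <- is.null(dim(points))
  pts <- rbind(points)
  nrm <- sqrt(sum(axis_dir^2))
  if (nrm < 1e-12) abort("axis direction has zero length")
  k <- axis_dir / nrm
  theta <- angle_deg * pi / 180
  v <- sweep(pts, 2, axis_point, "-")
  kv <- v %*% k                       # component along axis
  cross <- cbind(k[2] * v[, 3] - k[3] * v[, 2],
                 k[3] * v[, 1] - k[1] * v[, 3],
                 k[1] * v[, 2] - k[2] * v[, 1])
  rot <- v * cos(theta) + cross * sin(theta) +
    outer(as.numeric(kv), k) * (1 - cos(theta))
  out <- sweep(rot, 2, axis_point, "+")
  if (was_vec) as.numeric(out) else out
}

#' Construct a diyne-linker PROTAC model
#'
#' Partitions a PROTAC atom table into a fixed warhead (target-protein
#' side), a mobile warhead (E3-ligase side), and the four sp carbons of
#' the linear diyne linker. The rotation axis is the total-least-squares
#' best-fit line through the linker carbons, anchored at their centroid.
#' Because the diyne is essentially linear, rotation about this axis is
#' the ligand's only conformational degree of freedom.
#'
#' @param atoms `atom_tbl` of the whole PROTAC.
#' @param warhead_fixed,warhead_mobile,linker integer row indices into
#'   `atoms`; must be disjoint and cover every atom, with exactly 4
#'   linker carbons.
#' @param collinearity_tol_deg maximum allowed angle (degrees) between
#'   any linker bond and the fitted axis; looser geometries are rejected
#'   rather than scanned about an ill-defined axis.
#' @return object of class `diyne_ligand` with the partition, the axis
#'   point and unit direction.
#' @export
diyne_ligand <- function(atoms, warhead_fixed, warhead_mobile, linker,
                         collinearity_tol_deg = 5) {
  n <- nrow(atoms)
  idx <- c(warhead_fixed, warhead_mobile, linker)
  if (anyDuplicated(idx) > 0) abort("atom partition sets must be disjoint")
  if (!setequal(idx, seq_len(n))) {
    abort("partition sets must cover every atom of the ligand")
  }
  if (length(linker) != 4) abort("diyne linker must have exactly 4 carbons")
  lx <- coords(atoms)[linker, , drop = FALSE]
  ctr <- colMeans(lx)
  sv <- svd(sweep(lx, 2, ctr, "-"))
  dir <- sv$v[, 1]
  # orient along increasing order of the linker atoms
  if (sum((lx[4, ] - lx[1, ]) * dir) < 0) dir <- -dir
  bonds <- diff(lx)
  ang <- apply(bonds, 1, function(b) {
    acos(pmin(1, abs(sum(b * dir)) / sqrt(sum(b^2)))) * 180 / pi
  })
  if (max(ang) > collinearity_tol_deg) {
    abort(sprintf(
      "linker deviates from collinearity by %.2f deg (tolerance %.1f deg)",
      max(ang), collinearity_tol_deg))
  }
  structure(list(atoms = atoms,
                 warhead_fixed = sort(warhead_fixed),
                 warhead_mobile = sort(warhead_mobile),
                 linker = sort(linker),
                 axis_point = ctr,
                 axis_dir = dir / sqrt(sum(dir^2))),
            class = "diyne_ligand")
}

#' @export
print.diyne_ligand <- function(x, ...) {
  cat(sprintf(
    "<diyne_ligand> %d atoms (%d fixed warhead, %d mobile warhead, 4 linker)\n",
    nrow(x$atoms), length(x$warhead_fixed), length(x$warhead_mobile)))
  invisible(x)
}

#' Enumerate linker-dihedral conformers
#'
#' Systematically rotates the mobile warhead about the diyne axis in
#' `step_deg` increments with the warhead internal conformations fixed,
#' producing the full dihedral grid (36 conformers at the default 10
#' degree step). Fixed-warhead and linker atoms are bitwise identical
#' across conformers.
#'
#' @param ligand a `diyne_ligand`.
#' @param step_deg grid spacing in degrees; must divide 360.
#' @return object of class `conformer_set`: list with `conformers`
#'   (list of `atom_tbl`), `angles_deg`, `step_deg` and the input
#'   `ligand`.
#' @export
enumerate_conformers <- function(ligand, step_deg = 10) {
  if (!inherits(ligand, "diyne_ligand")) abort("ligand must be a diyne_ligand")
  if (step_deg <= 0 || abs(360 / step_deg - round(360 / step_deg)) > 1e-9) {
    abort(sprintf("step_deg (%s) must divide 360", format(step_deg)))
  }
  angles <- seq(0, 360 - step_deg, by = step_deg)
  mob <- ligand$warhead_mobile
  base_xyz <- coords(ligand$atoms)
  conformers <- lapply(angles, function(a) {
    if (a == 0) return(ligand$atoms)
    xyz <- base_xyz
    xyz[mob, ] <- rotate_about_axis(base_xyz[mob, , drop = FALSE],
                                    ligand$axis_point, ligand$axis_dir, a)
    set_coords(ligand$atoms, xyz)
  })
  structure(list(conformers = conformers, angles_deg = angles,
                 step_deg = step_deg, ligand = ligand),
            class = "conformer_set")
}

#' @export
print.conformer_set <- function(x, ...) {
  cat(sprintf("<conformer_set> %d conformers, %g deg grid\n",
              length(x$conformers), x$step_deg))
  invisible(x)
}

#' @export
length.conformer_set <- function(x) length(x$conformers)

#' Export a conformer set as a multi-model PDB
#'
#' One MODEL per grid angle, in grid order; the angle is recorded in a
#' REMARK line preceding each model.
#'
#' @param conformers a `conformer_set`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_conformers_pdb <- function(conformers, path) {
  frames <- conformers$conformers
  write_multimodel_pdb(frames, path,
                       remarks = sprintf("REMARK 250 DIHEDRAL_DEG %g",
                                         conformers$angles_deg))
}
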