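#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD
#' between `mobile` (moved) and `reference` (fixed) ordered point sets.
#' Reflections are corrected via the determinant sign fix, so a mirror
#' fit is never returned.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3, in
#'   one-to-one correspondence; the points must not be collinear.
#' @param weights optional non-negative per-point weights (default
#'   uniform).
#' @return list with `transform` (a [rigid_transform]) and `rmsd`
#'   (angstrom, the minimised value, weighted if weights are given).
#' @export
kabsch <- function(mobile, reference, weights = NULL) {
  mobile <- rbind(mobile)
  reference <- rbind(reference)
  n <- nrow(mobile)
  if (n != nrow(reference)) abort("point sets must have equal length")
  if (n < 3) abort("superposition needs at least 3 point pairs")
  w <- weights %||% rep(1, n)
  if (length(w) != n || any(w < 0) || sum(w) == 0) {
    abort("weights must be non-negative with positive sum")
  }
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  P <- sweep(mobile, 2, cm, "-")
  Q <- sweep(reference, 2, cr, "-")
  sv_ref <- svd(Q * sqrt(w))$d
  if (sv_ref[2] < 1e-8 * max(sv_ref[1], 1e-12)) {
    abort("degenerate geometry: mapped points are (near-)collinear")
  }
  H <- t(P * w) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cr - R %*% cm)
  fitted <- P %*% t(R)
  rmsd_val <- sqrt(sum(w * rowSums((fitted - Q)^2)))
  list(transform = rigid_transform(R, tr), rmsd = rmsd_val)
}

#' Root-mean-square deviation between paired point sets
#'
#' Direct RMSD with no superposition: superposition is an explicit,
#' separate step ([kabsch]).
#'
#' @param a,b n x 3 coordinate matrices in correspondence, n >= 1.
#' @return RMSD in angstrom.
#' @export
rmsd <- function(a, b) {
  a <- rbind(a)
  b <- rbind(b)
  if (nrow(a) != nrow(b)) abort("point sets must have equal length")
  if (nrow(a) == 0) abort("point sets must be non-empty")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Read a warhead atom map
#'
#' Two-column whitespace-delimited text: the atom name in the
#' protein-ligand complex and the matching PROTAC warhead atom name.
#' Lines starting with `#` are ignored. Maps are explicit inputs by
#' design; no substructure matching is attempted.
#'
#' @param path map file path.
#' @return tibble with columns `complex_atom`, `protac_atom`.
#' @export
read_atom_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read atom map '%s'", path))
  lines <- grep("^\\s*(#|$)", readLines(path, warn = FALSE),
                invert = TRUE, value = TRUE)
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(fields) != 2)
  if (length(bad) > 0) {
    abort(sprintf("atom map '%s': line %d does not have 2 fields",
                  path, bad[1]))
  }
  atom_map(vapply(fields, `[`, "", 1), vapply(fields, `[`, "", 2))
}

#' Construct a warhead atom map
#'
#' @param complex_atom atom names of the bound ligand in the protein
#'   complex.
#' @param protac_atom matching atom names in the PROTAC warhead.
#' @return tibble of class `atom_map`.
#' @export
atom_map <- function(complex_atom, protac_atom) {
  if (length(complex_atom) != length(protac_atom)) {
    abort("map columns must have equal length")
  }
  if (anyDuplicated(complex_atom) || anyDuplicated(protac_atom)) {
    abort("atom map names must be unique on each side")
  }
  structure(tibble(complex_atom = as.character(complex_atom),
                   protac_atom = as.character(protac_atom)),
            class = c("atom_map", class(tibble())))
}

#' Write an atom map to delimited text
#' @param map an `atom_map`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_atom_map <- function(map, path) {
  writeLines(paste(map$complex_atom, map$protac_atom), path)
  invisible(path)
}

#' Pose a protein-ligand complex onto a PROTAC warhead
#'
#' Fits a rigid transform on the mapped ligand atoms only (uniform
#' weights), then moves the whole complex - protein and bound ligand -
#' by that transform, so the complex's internal geometry is preserved
#' exactly. The mapped-atom RMSD is recorded in the result's
#' `mapped_rmsd` attribute.
#'
#' @param complex an `atom_tbl` containing the protein and its bound
#'   ligand.
#' @param map an [atom_map] pairing complex ligand atom names with
#'   PROTAC warhead atom names.
#' @param conformer an `atom_tbl` of the PROTAC conformer to pose onto.
#' @return the posed complex (`atom_tbl`) with attributes
#'   `mapped_rmsd` and `transform`.
#' @export
align_partner <- function(complex, map, conformer) {
  src_idx <- match(map$complex_atom, complex$name)
  dst_idx <- match(map$protac_atom, conformer$name)
  if (anyNA(src_idx)) {
    abort(sprintf("map atoms not found in complex: %s",
                  paste(map$complex_atom[is.na(src_idx)], collapse = ", ")))
  }
  if (anyNA(dst_idx)) {
    abort(sprintf("map atoms not found in PROTAC conformer: %s",
                  paste(map$protac_atom[is.na(dst_idx)], collapse = ", ")))
  }
  fit <- kabsch(coords(complex)[src_idx, , drop = FALSE],
                coords(conformer)[dst_idx, , drop = FALSE])
  posed <- apply_transform(complex, fit$transform)
  attr(posed, "mapped_rmsd") <- fit$rmsd
  attr(posed, "transform") <- fit$transform
  posed
}
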