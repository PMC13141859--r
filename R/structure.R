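#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

#' Build an atom table
#'
#' An atom table is a tibble with one row per atom and the columns
#' `element`, `name`, `residue_index`, `residue_name`, `chain`,
#' `x`, `y`, `z`, plus derived flags `is_backbone`, `is_heavy`,
#' `is_calpha`, `is_het` and a stable `atom_id` indexing into the
#' originally constructed table. Selections and rigid transforms
#' preserve row order and `atom_id`, so subsets remain addressable
#' views into their parent structure.
#'
#' @param atoms data frame with at least `element`, `name`,
#'   `residue_index`, `residue_name`, `chain`, `x`, `y`, `z`. An
#'   optional logical `is_het` marks non-polymer (HETATM) atoms.
#' @param label free-text label for the structure (e.g. `"BRD4 BD1"`).
#' @param source optional provenance string (file path, generator call).
#' @return a tibble of class `atom_tbl`.
#' @export
atom_tbl <- function(atoms, label = NULL, source = NULL) {
  req <- c("element", "name", "residue_index", "residue_name", "chain",
           "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atom table lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  atoms <- as_tibble(atoms)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("atom coordinates must be finite")
  }
  if (is.null(atoms[["is_het"]])) atoms$is_het <- FALSE
  atoms$element <- toupper(trimws(atoms$element))
  atoms$name <- trimws(atoms$name)
  atoms$is_heavy <- atoms$element != "H"
  atoms$is_backbone <- !atoms$is_het & atoms$name %in% BACKBONE_NAMES
  atoms$is_calpha <- atoms$is_backbone & atoms$name == "CA"
  if (is.null(atoms[["atom_id"]])) atoms$atom_id <- seq_len(nrow(atoms))
  out <- atoms[, unique(c("atom_id", req, "is_het", "is_backbone",
                          "is_heavy", "is_calpha",
                          setdiff(names(atoms), c("atom_id", req, "is_het",
                                                  "is_backbone", "is_heavy",
                                                  "is_calpha"))))]
  new_atom_tbl(out, label = label, source = source)
}

new_atom_tbl <- function(df, label = NULL, source = NULL) {
  structure(df,
            class = unique(c("atom_tbl", class(as_tibble(df)))),
            label = label %||% attr(df, "label"),
            source = source %||% attr(df, "source"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.atom_tbl <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("<atom_tbl> %d atoms%s\n", nrow(x),
              if (!is.null(lab)) paste0(" - ", lab) else ""))
  NextMethod()
}

#' Coordinates of an atom table as an n x 3 matrix
#' @param structure an `atom_tbl`.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(structure) {
  cbind(x = structure$x, y = structure$y, z = structure$z)
}

set_coords <- function(structure, xyz) {
  structure$x <- xyz[, 1]
  structure$y <- xyz[, 2]
  structure$z <- xyz[, 3]
  structure
}

#' Select atoms by predicate
#'
#' Filters an atom table with dplyr-style expressions over its columns
#' (`is_calpha`, `is_backbone`, `is_heavy`, `is_het`, `chain`, `name`,
#' `residue_index`, ...). Row order and `atom_id` are preserved, so the
#' result is a view into the parent structure; an empty selection is a
#' valid empty view.
#'
#' @param structure an `atom_tbl`.
#' @param ... filter expressions, combined with AND.
#' @return an `atom_tbl` containing exactly the matching atoms.
#' @export
select_atoms <- function(structure, ...) {
  out <- dplyr::filter(as_tibble(structure), ...)
  new_atom_tbl(out, label = attr(structure, "label"),
               source = attr(structure, "source"))
}

#' Select atoms with a predicate string
#'
#' Config-friendly selection syntax: whitespace-separated terms are
#' ANDed. Terms: `calpha`, `backbone`, `heavy`, `protein` (non-HETATM),
#' `ligand` (HETATM), `chain=A,B`, `name=CA,N`, `resname=LIG`, `all`.
#'
#' @param structure an `atom_tbl`.
#' @param selection selection string.
#' @return an `atom_tbl` view.
#' @export
select_str <- function(structure, selection) {
  keep <- selection_mask(structure, selection)
  new_atom_tbl(as_tibble(structure)[keep, , drop = FALSE],
               label = attr(structure, "label"),
               source = attr(structure, "source"))
}

selection_mask <- function(structure, selection) {
  terms <- strsplit(trimws(selection), "\\s+")[[1]]
  keep <- rep(TRUE, nrow(structure))
  for (term in terms) {
    keep <- keep & switch(
      sub("=.*$", "", term),
      all = TRUE,
      calpha = structure$is_calpha,
      backbone = structure$is_backbone,
      heavy = structure$is_heavy,
      protein = !structure$is_het,
      ligand = structure$is_het,
      chain = structure$chain %in% strsplit(sub("^chain=", "", term), ",")[[1]],
      name = structure$name %in% strsplit(sub("^name=", "", term), ",")[[1]],
      resname = structure$residue_name %in%
        strsplit(sub("^resname=", "", term), ",")[[1]],
      abort(sprintf("unknown selection term '%s'", term))
    )
  }
  keep
}

#' Rigid-body transform
#'
#' A proper rotation plus translation acting on coordinates in
#' angstroms: `x -> R x + t`. The rotation must be orthonormal with
#' determinant +1 (tolerance 1e-8).
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation vector (angstrom).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)) || length(translation) != 3) {
    abort("rigid_transform needs a 3x3 rotation and a 3-vector translation")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8) {
    abort("rotation must be orthonormal with determinant +1")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\nrotation:\n")
  print(round(x$rotation, 6))
  cat("translation:", paste(round(x$translation, 6), collapse = " "), "\n")
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` applies `b` first, then `a`.
#' @param a,b `rigid_transform` objects.
#' @return the composed `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation), as.numeric(-t(t$rotation) %*% t$translation))
}

#' Apply a rigid transform to a structure
#'
#' Every coordinate x is replaced by `R x + t`; pairwise distances are
#' preserved to numerical precision.
#'
#' @param structure an `atom_tbl`.
#' @param transform a `rigid_transform`.
#' @return the transformed `atom_tbl` (same atoms, same order).
#' @export
apply_transform <- function(structure, transform) {
  if (!inherits(transform, "rigid_transform")) {
    abort("transform must be a rigid_transform")
  }
  xyz <- coords(structure) %*% t(transform$rotation)
  xyz <- sweep(xyz, 2, transform$translation, "+")
  set_coords(structure, xyz)
}

#' Read a PDB file into an atom table
#'
#' Parses fixed-width ATOM/HETATM records. Hydrogens are dropped by
#' default (the clash census concerns heavy atoms only). For alternate
#' locations the highest-occupancy record is kept; ties go to altloc
#' 'A', then the first encountered. Backbone flags are set for atom
#' names N, CA, C, O (and OXT) of polymer residues; HETATM atoms are
#' never flagged backbone.
#'
#' @param path PDB file path.
#' @param keep_hydrogens keep H atoms (default FALSE).
#' @param label optional structure label (defaults to the file name).
#' @return an `atom_tbl`.
#' @export
read_pdb <- function(path, keep_hydrogens = FALSE, label = NULL) {
  if (!file.exists(path)) abort(sprintf("cannot read PDB file '%s'", path))
  raw <- readLines(path, warn = FALSE)
  n_rec <- sum(grepl("^(ATOM  |HETATM)", raw))
  if (n_rec == 0) {
    abort(sprintf("no ATOM/HETATM records parsed from '%s' (%d lines read)",
                  path, length(raw)))
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  at$elesy[is.na(at$elesy) | at$elesy == ""] <-
    substr(trimws(at$elety[is.na(at$elesy) | at$elesy == ""]), 1, 1)
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1
  # altloc resolution: highest occupancy, tie -> 'A', then first seen
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
  ord <- order(match(key, unique(key)), -at$o, at$alt != "A",
               seq_len(nrow(at)))
  at <- at[ord, ]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$resid,
                             at$elety, sep = "|")), ]
  at <- at[order(at$eleno), ]
  out <- atom_tbl(
    tibble(element = toupper(trimws(at$elesy)),
           name = trimws(at$elety),
           residue_index = at$resno,
           residue_name = trimws(at$resid),
           chain = ifelse(is.na(at$chain), "", at$chain),
           x = at$x, y = at$y, z = at$z,
           is_het = at$type == "HETATM"),
    label = label %||% basename(path), source = path)
  if (!keep_hydrogens) out <- select_atoms(out, .data$is_heavy)
  out
}

#' Write an atom table to a PDB file
#'
#' Fixed-width ATOM/HETATM records; coordinates at 3 decimal places.
#' Atom serials beyond 99999 follow bio3d's overflow convention.
#'
#' @param structure a non-empty `atom_tbl`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  if (nrow(structure) == 0) abort("refusing to write an empty structure")
  bio3d::write.pdb(
    pdb = NULL, file = path,
    type = ifelse(structure$is_het, "HETATM", "ATOM"),
    xyz = as.numeric(t(coords(structure))),
    resno = structure$residue_index,
    resid = structure$residue_name,
    eleno = seq_len(nrow(structure)),
    elety = structure$name,
    chain = ifelse(structure$chain == "", " ", structure$chain),
    elesy = structure$element)
  invisible(path)
}
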