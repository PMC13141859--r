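#' Count steric clashes between two structures
#'
#' A clash is an unordered inter-structure heavy-atom pair at distance
#' strictly less than `cutoff` (default 2.4 angstrom). The backbone
#' subcount requires both atoms to carry the backbone flag. Two paths
#' are provided - a naive all-pairs census and a cell-list accelerated
#' census - which return identical counts.
#'
#' @param a,b non-empty `atom_tbl`s (only heavy atoms are considered).
#' @param cutoff clash distance cutoff in angstrom; must be positive.
#' @param method `"cell"` (default) or `"naive"`.
#' @param detail if TRUE, attach the clashing pair list (atom ids and
#'   distances) as the `pairs` attribute.
#' @return one-row tibble of class `clash_report` with
#'   `backbone_pairs`, `heavy_pairs`, `cutoff`.
#' @export
count_clashes <- function(a, b, cutoff = 2.4,
                          method = c("cell", "naive"), detail = FALSE) {
  method <- match.arg(method)
  if (cutoff <= 0) abort("cutoff must be positive")
  if (nrow(a) == 0 || nrow(b) == 0) abort("structures must be non-empty")
  ah <- select_atoms(a, .data$is_heavy)
  bh <- select_atoms(b, .data$is_heavy)
  pairs <- if (method == "naive") {
    clash_pairs_naive(ah, bh, cutoff)
  } else {
    clash_pairs_cell(ah, bh, cutoff)
  }
  bb <- ah$is_backbone[pairs$i] & bh$is_backbone[pairs$j]
  report <- tibble(backbone_pairs = sum(bb),
                   heavy_pairs = nrow(pairs),
                   cutoff = cutoff)
  report <- structure(report, class = c("clash_report", class(tibble())))
  if (detail) {
    attr(report, "pairs") <- tibble(atom_a = ah$atom_id[pairs$i],
                                    atom_b = bh$atom_id[pairs$j],
                                    distance = pairs$d,
                                    backbone = bb)
  }
  report
}

clash_pairs_naive <- function(ah, bh, cutoff) {
  xa <- coords(ah)
  xb <- coords(bh)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  tibble(i = hit[, 1], j = hit[, 2],
         d = sqrt(pmax(d2[hit], 0)))
}

clash_pairs_cell <- function(ah, bh, cutoff) {
  xa <- coords(ah)
  xb <- coords(bh)
  cell_a <- floor(xa / cutoff)
  cell_b <- floor(xb / cutoff)
  key_b <- paste(cell_b[, 1], cell_b[, 2], cell_b[, 3])
  buckets <- split(seq_len(nrow(xb)), key_b)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  res_i <- integer(0); res_j <- integer(0); res_d <- numeric(0)
  for (i in seq_len(nrow(xa))) {
    neigh <- sweep(offsets, 2, cell_a[i, ], "+")
    keys <- paste(neigh[, 1], neigh[, 2], neigh[, 3])
    cand <- unlist(buckets[keys], use.names = FALSE)
    if (length(cand) == 0) next
    d2 <- rowSums(sweep(xb[cand, , drop = FALSE], 2, xa[i, ], "-")^2)
    hit <- d2 < cutoff^2
    if (any(hit)) {
      res_i <- c(res_i, rep(i, sum(hit)))
      res_j <- c(res_j, cand[hit])
      res_d <- c(res_d, sqrt(d2[hit]))
    }
  }
  tibble(i = res_i, j = res_j, d = res_d)
}

#' Viability rule for a posed ternary complex
#'
#' A pose is viable iff it has no backbone-backbone clashes and at most
#' `max_heavy` total heavy-atom clashes ("greater than 20" rejection is
#' strict: 20 heavy clashes is viable, 21 is not).
#'
#' @param report a `clash_report` (from [count_clashes]).
#' @param max_heavy maximum tolerated heavy-atom clash pairs.
#' @return logical.
#' @export
is_viable <- function(report, max_heavy = 20) {
  report$backbone_pairs == 0 & report$heavy_pairs <= max_heavy
}

#' Screen a conformer grid for viable ternary poses
#'
#' For each linker-dihedral conformer, poses both protein-ligand
#' complexes onto their warheads ([align_partner]), counts inter-protein
#' clashes, and applies the viability rule. By default the census is
#' protein-vs-protein only (HETATM ligand atoms are excluded, since
#' warhead placement reproduces the crystallographic binding pose);
#' `include_ligand = TRUE` adds ligand atoms to the census. Accessory
#' chains can be trimmed with the selection strings.
#'
#' @param conformers a `conformer_set`.
#' @param complex_a,complex_b `atom_tbl`s of the two protein-ligand
#'   complexes (e.g. target protein and E3 ligase sides).
#' @param map_a,map_b [atom_map]s pairing each complex's ligand atoms
#'   with its PROTAC warhead.
#' @param cutoff clash cutoff, angstrom.
#' @param max_heavy heavy-clash tolerance for viability.
#' @param include_ligand include HETATM atoms in the clash census.
#' @param selection_a,selection_b optional [select_str] selection
#'   strings restricting each side's census atoms (e.g. to drop an
#'   accessory chain).
#' @param method clash census path, `"cell"` or `"naive"`.
#' @param keep_poses if TRUE, attach the posed structures as the
#'   `poses` attribute (list of lists with `pose_a`, `pose_b`,
#'   `ligand`).
#' @return tibble of class `ternary_screen` with one row per grid
#'   angle: `angle`, `backbone_pairs`, `heavy_pairs`, `viable`.
#' @export
screen_conformers <- function(conformers, complex_a, map_a,
                              complex_b, map_b,
                              cutoff = 2.4, max_heavy = 20,
                              include_ligand = FALSE,
                              selection_a = NULL, selection_b = NULL,
                              method = c("cell", "naive"),
                              keep_poses = FALSE) {
  method <- match.arg(method)
  census <- function(pose, selection) {
    out <- if (include_ligand) pose else select_atoms(pose, !.data$is_het)
    if (!is.null(selection)) out <- select_str(out, selection)
    out
  }
  rows <- vector("list", length(conformers$conformers))
  poses <- if (keep_poses) vector("list", length(rows)) else NULL
  for (k in seq_along(conformers$conformers)) {
    conf <- conformers$conformers[[k]]
    angle <- conformers$angles_deg[k]
    pose_a <- tryCatch(align_partner(complex_a, map_a, conf),
                       error = function(e) abort(sprintf(
                         "alignment of side A failed at angle %g: %s",
                         angle, conditionMessage(e))))
    pose_b <- tryCatch(align_partner(complex_b, map_b, conf),
                       error = function(e) abort(sprintf(
                         "alignment of side B failed at angle %g: %s",
                         angle, conditionMessage(e))))
    rep <- count_clashes(census(pose_a, selection_a),
                         census(pose_b, selection_b),
                         cutoff = cutoff, method = method)
    rows[[k]] <- tibble(angle = angle,
                        backbone_pairs = rep$backbone_pairs,
                        heavy_pairs = rep$heavy_pairs,
                        viable = is_viable(rep, max_heavy))
    if (keep_poses) {
      poses[[k]] <- list(pose_a = pose_a, pose_b = pose_b, ligand = conf)
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- structure(out, class = c("ternary_screen", class(tibble())),
                   params = list(cutoff = cutoff, max_heavy = max_heavy,
                                 include_ligand = include_ligand,
                                 selection_a = selection_a,
                                 selection_b = selection_b,
                                 step_deg = conformers$step_deg),
                   poses = poses)
  out
}

#' @export
print.ternary_screen <- function(x, ...) {
  cat(sprintf("<ternary_screen> %d viable of %d conformers\n",
              sum(x$viable), nrow(x)))
  NextMethod()
}
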