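#' Staged harmonic-restraint release schedule
#'
#' The relaxation protocol minimises the posed complex in four stages,
#' each with harmonic positional restraints (default force constant 10
#' kcal mol^-1 A^-2) on a shrinking atom set: (1) all protein and
#' ligand heavy atoms; (2) release the protein sidechains (backbone and
#' ligand stay restrained); (3) release the protein backbone (ligand
#' only); (4) release the ligand (unrestrained). Restrained sets are
#' non-increasing by construction: each stage releases atoms, never
#' re-restrains them.
#'
#' @param force_constant harmonic force constant, kcal mol^-1 A^-2.
#' @return tibble of class `restraint_schedule` with columns `stage`,
#'   `restrained` (a token understood by [restrained_indices]),
#'   `force_constant`, `action`.
#' @export
build_restraint_schedule <- function(force_constant = 10) {
  if (force_constant < 0) abort("force_constant must be non-negative")
  out <- tibble(
    stage = 1:4,
    restrained = c("all_heavy", "backbone_and_ligand", "ligand_only", "none"),
    force_constant = force_constant,
    action = "minimize")
  structure(out, class = c("restraint_schedule", class(tibble())))
}

#' Resolve a restraint token to atom row indices
#'
#' @param structure an `atom_tbl`.
#' @param restrained one of `"all_heavy"`, `"backbone_and_ligand"`,
#'   `"ligand_only"`, `"none"`.
#' @return integer row indices of the restrained atoms.
#' @export
restrained_indices <- function(structure, restrained) {
  switch(restrained,
         all_heavy = which(structure$is_heavy),
         backbone_and_ligand = which(structure$is_heavy &
                                       (structure$is_backbone |
                                          structure$is_het)),
         ligand_only = which(structure$is_heavy & structure$is_het),
         none = integer(0),
         abort(sprintf("unknown restraint token '%s'", restrained)))
}

#' Export a restraint schedule as a structured text report
#'
#' Engine-agnostic description usable to configure any MD package.
#' @param schedule a `restraint_schedule`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_restraint_schedule <- function(schedule, path) {
  lines <- c("# staged harmonic-restraint release schedule",
             sprintf("stage %d: action=%s restrained=%s force_constant=%g kcal/mol/A^2",
                     schedule$stage, schedule$action, schedule$restrained,
                     schedule$force_constant))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a trajectory
#'
#' @param frames list of `atom_tbl` snapshots with identical atom
#'   rosters.
#' @param times_ns strictly increasing frame times in nanoseconds.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(frames, times_ns) {
  if (length(frames) != length(times_ns)) {
    abort("frames and times_ns must have equal length")
  }
  if (length(times_ns) > 1 && any(diff(times_ns) <= 0)) {
    abort("frame times must be strictly increasing")
  }
  if (length(frames) > 1) {
    roster <- paste(frames[[1]]$name, frames[[1]]$residue_index,
                    frames[[1]]$chain)
    for (f in frames[-1]) {
      if (!identical(paste(f$name, f$residue_index, f$chain), roster)) {
        abort("all frames must share an identical atom roster")
      }
    }
  }
  structure(list(frames = frames, times_ns = as.numeric(times_ns)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames, %g-%g ns, %d atoms\n",
              length(x$frames),
              if (length(x$times_ns)) min(x$times_ns) else NA,
              if (length(x$times_ns)) max(x$times_ns) else NA,
              if (length(x$frames)) nrow(x$frames[[1]]) else 0))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$frames)

#' Discard equilibration frames
#'
#' Retains frames with time strictly greater than `discard_ns`
#' (default 10 ns), preserving order. Idempotent for a fixed cutoff.
#'
#' @param traj a `trajectory`.
#' @param discard_ns equilibration period to discard, ns.
#' @return the filtered `trajectory`; a warning is raised if every
#'   frame is discarded.
#' @export
equilibration_filter <- function(traj, discard_ns = 10) {
  keep <- traj$times_ns > discard_ns
  if (!any(keep)) {
    warn(sprintf("all %d frames fall within the %g ns equilibration window",
                 length(traj$frames), discard_ns))
  }
  trajectory(traj$frames[keep], traj$times_ns[keep])
}

#' Select the representative (medoid) frame
#'
#' For each frame i, every other frame j is superposed onto i using the
#' alignment selection (Kabsch, per comparison), the RMSD is computed
#' over the RMSD selection, and the median over j != i is taken (an
#' even count uses the midpoint average; a single frame has median 0).
#' The frame minimising this median RMSD is returned; ties break to the
#' lowest index. The intended use mirrors ternary-complex ensembles:
#' align on the E3-ligase backbone, measure RMSD over the target
#' protein's C-alpha atoms.
#'
#' @param traj a `trajectory` with at least one frame.
#' @param align_selection,rmsd_selection [select_str] selection strings
#'   evaluated on the shared roster; both must select at least one atom
#'   (and the alignment selection at least 3).
#' @return list of class `representative_frame`: `index`, `time_ns`,
#'   `median_rmsd`, and the per-frame `summary` tibble.
#' @export
select_representative <- function(traj, align_selection, rmsd_selection) {
  n <- length(traj$frames)
  if (n == 0) abort("trajectory has no frames")
  roster <- traj$frames[[1]]
  ai <- which(selection_mask(roster, align_selection))
  ri <- which(selection_mask(roster, rmsd_selection))
  if (length(ai) < 3) abort("alignment selection must cover >= 3 atoms")
  if (length(ri) < 1) abort("RMSD selection is empty")
  axyz <- lapply(traj$frames, function(f) coords(f)[ai, , drop = FALSE])
  rxyz <- lapply(traj$frames, function(f) coords(f)[ri, , drop = FALSE])
  med <- vapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    if (length(others) == 0) return(0)
    vals <- vapply(others, function(j) {
      fit <- kabsch(axyz[[j]], axyz[[i]])
      moved <- sweep(rxyz[[j]] %*% t(fit$transform$rotation), 2,
                     fit$transform$translation, "+")
      rmsd(moved, rxyz[[i]])
    }, numeric(1))
    stats::median(vals)
  }, numeric(1))
  best <- which.min(med)  # which.min breaks ties to the lowest index
  structure(list(index = best,
                 time_ns = traj$times_ns[best],
                 median_rmsd = med[best],
                 summary = tibble(frame = seq_len(n),
                                  time_ns = traj$times_ns,
                                  median_rmsd = med)),
            class = "representative_frame")
}

#' @export
print.representative_frame <- function(x, ...) {
  cat(sprintf(
    "<representative_frame> frame %d (t = %g ns), median RMSD %.4f A\n",
    x$index, x$time_ns, x$median_rmsd))
  invisible(x)
}

#' Toy restrained minimisation
#'
#' A deliberately simple stand-in energy model that makes the staged
#' restraint-release semantics testable: pairwise soft-sphere repulsion
#' `(sigma/r)^12` (sigma defaulting to the 2.4 A clash cutoff) plus a
#' harmonic positional restraint `k |x - x_ref|^2` over the stage's
#' restrained set. Steepest descent with backtracking: the energy never
#' increases between accepted iterations. This is not an MD engine and
#' is not intended to produce physical ensembles.
#'
#' @param structure starting `atom_tbl`.
#' @param reference restraint reference `atom_tbl` (same roster).
#' @param stage one row of a [build_restraint_schedule] tibble (or any
#'   list with `restrained` and `force_constant`).
#' @param sigma soft-sphere radius, angstrom.
#' @param epsilon repulsion scale, kcal mol^-1.
#' @param max_steps iteration cap.
#' @param tol convergence threshold on the gradient max-norm.
#' @return the minimised `atom_tbl`, with the energy trace in the
#'   `energy_trace` attribute.
#' @export
restrained_minimize <- function(structure, reference, stage,
                                sigma = 2.4, epsilon = 1,
                                max_steps = 500, tol = 1e-4) {
  if (nrow(structure) != nrow(reference) ||
      !identical(structure$name, reference$name)) {
    abort("structure and reference must share the same atom roster")
  }
  k <- stage$force_constant
  res <- restrained_indices(structure, stage$restrained)
  xyz <- coords(structure)
  ref <- coords(reference)
  n <- nrow(xyz)

  energy_grad <- function(x) {
    e <- 0
    g <- matrix(0, n, 3)
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        dv <- sweep(x[(i + 1):n, , drop = FALSE], 2, x[i, ], "-")
        r2 <- rowSums(dv^2)
        near <- r2 < (3 * sigma)^2  # repulsion negligible beyond this
        if (any(near)) {
          r2n <- r2[near]
          inv <- (sigma^2 / r2n)^6
          e <- e + epsilon * sum(inv)
          # dE/dr * unit vector = -12 eps inv / r2 * dv
          coef <- -12 * epsilon * inv / r2n
          gi <- dv[near, , drop = FALSE] * coef
          g[i, ] <- g[i, ] - colSums(gi)
          jj <- ((i + 1):n)[near]
          g[jj, ] <- g[jj, , drop = FALSE] + gi
        }
      }
    }
    if (length(res) > 0 && k > 0) {
      dd <- x[res, , drop = FALSE] - ref[res, , drop = FALSE]
      e <- e + k * sum(dd^2)
      g[res, ] <- g[res, , drop = FALSE] + 2 * k * dd
    }
    list(e = e, g = g)
  }

  eg <- energy_grad(xyz)
  trace <- eg$e
  step <- 0.05
  for (it in seq_len(max_steps)) {
    gmax <- max(abs(eg$g))
    if (gmax < tol) break
    accepted <- FALSE
    for (try in 1:30) {
      cand <- xyz - step * eg$g / max(gmax, 1)
      ce <- energy_grad(cand)
      if (ce$e <= eg$e) {
        xyz <- cand
        eg <- ce
        step <- step * 1.2
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    trace <- c(trace, eg$e)
    if (!accepted) break
  }
  out <- set_coords(structure, xyz)
  attr(out, "energy_trace") <- trace
  out
}

# ---- multi-model PDB trajectory I/O -------------------------------------

#' Write structures as a multi-model PDB
#'
#' One MODEL/ENDMDL block per frame; an optional REMARK line precedes
#' each model (used to carry frame times or grid angles).
#'
#' @param frames list of `atom_tbl`s with identical rosters.
#' @param path output path.
#' @param remarks optional character vector, one REMARK line per frame.
#' @return invisibly, `path`.
#' @export
write_multimodel_pdb <- function(frames, path, remarks = NULL) {
  if (length(frames) == 0) abort("no frames to write")
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (k in seq_along(frames)) {
    if (!is.null(remarks)) writeLines(remarks[k], con)
    writeLines(sprintf("MODEL     %4d", k), con)
    write_pdb(frames[[k]], tmp)
    body <- readLines(tmp, warn = FALSE)
    writeLines(grep("^(ATOM  |HETATM)", body, value = TRUE), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB
#'
#' Frame times (ns) are stored in `REMARK 250 TIME_NS` lines preceding
#' each MODEL, so real MD outputs converted to this layout remain
#' analyzable.
#'
#' @param traj a `trajectory`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_trajectory_pdb <- function(traj, path) {
  write_multimodel_pdb(traj$frames, path,
                       remarks = sprintf("REMARK 250 TIME_NS %g",
                                         traj$times_ns))
}

#' Read a multi-model PDB as a trajectory
#'
#' Frame times are taken from `REMARK 250 TIME_NS` lines when present,
#' from a two-column sidecar table (`frame time_ns`) if supplied, and
#' otherwise default to the frame index in ns.
#'
#' @param path multi-model PDB path.
#' @param times_path optional whitespace-delimited sidecar with columns
#'   `frame` and `time_ns`.
#' @param keep_hydrogens keep H atoms.
#' @return a `trajectory`.
#' @export
read_trajectory_pdb <- function(path, times_path = NULL,
                                keep_hydrogens = FALSE) {
  if (!file.exists(path)) abort(sprintf("cannot read trajectory '%s'", path))
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0 || length(starts) != length(ends)) {
    # single-model file: treat the whole file as one frame
    frame <- read_pdb(path, keep_hydrogens = keep_hydrogens)
    return(trajectory(list(frame), 1))
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  frames <- lapply(seq_along(starts), function(k) {
    writeLines(c(lines[(starts[k] + 1):(ends[k] - 1)], "END"), tmp)
    read_pdb(tmp, keep_hydrogens = keep_hydrogens,
             label = sprintf("%s model %d", basename(path), k))
  })
  times <- as.numeric(seq_along(frames))
  rem <- grep("^REMARK 250 TIME_NS", lines, value = TRUE)
  if (length(rem) == length(frames)) {
    times <- as.numeric(sub("^REMARK 250 TIME_NS\\s+", "", rem))
  } else if (!is.null(times_path)) {
    tab <- utils::read.table(times_path, header = TRUE)
    times <- tab$time_ns[match(seq_along(frames), tab$frame)]
  }
  trajectory(frames, times)
}
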