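# High-level orchestration over the geometric and SPR stages. These
# functions consume a flat run configuration (YAML on disk or a named
# list), write their outputs plus a machine-readable provenance block
# under an output directory, and are what the thin command-line script
# in inst/cli/ dispatches to.

#' Default run configuration
#'
#' Defaults reproduce the published protocol parameters: 10 degree
#' dihedral grid, 2.4 angstrom clash cutoff, at most 20 heavy-atom
#' clashes, protein-vs-protein census, 10 ns equilibration discard,
#' binary (120 s / 180 s) and ternary (400 s / 600 s) injection
#' timings.
#'
#' @return named list of defaults.
#' @export
default_run_config <- function() {
  list(step_deg = 10, clash_cutoff = 2.4, max_heavy = 20,
       include_ligand = FALSE, selection_a = NULL, selection_b = NULL,
       discard_ns = 10,
       align_selection = "backbone chain=B", rmsd_selection = "calpha chain=A",
       spr = list(format = "ternary", top = 1e-6, fold = 2, n_points = 5,
                  contact_time = 400, dissociation_time = 600,
                  noise_sd = 0, k_on = 1.47e5, k_off = 0.0085, rmax = 100),
       seed = 1, out_dir = "protacscreen_run")
}

#' Read a run configuration file
#'
#' YAML key/value file; missing keys fall back to
#' [default_run_config]. Values supplied in `overrides` (e.g. parsed
#' command-line flags) win over both.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @param overrides named list of overriding values.
#' @return configuration list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("config file '%s' not found", path))
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  }
  utils::modifyList(cfg, overrides)
}

provenance_block <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  list(config_hash = unname(tools::md5sum(tmp)),
       seed = cfg$seed,
       package_version = as.character(utils::packageVersion("protacscreen")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

write_report <- function(report, cfg, path) {
  report$provenance <- provenance_block(cfg)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

load_ligand_from_config <- function(cfg) {
  atoms <- read_pdb(cfg$ligand_pdb)
  nm <- atoms$name
  diyne_ligand(atoms,
               warhead_fixed = which(nm %in% cfg$warhead_fixed),
               warhead_mobile = which(nm %in% cfg$warhead_mobile),
               linker = which(nm %in% cfg$linker))
}

#' Run the conformer scan and viability screen
#'
#' Enumerates the dihedral grid, poses both complexes per conformer,
#' applies the clash viability rule, and writes `viability.csv`,
#' `viable_poses.pdb` (multi-model, ligand conformers of the viable
#' angles) and `scan_summary.json` under the output directory.
#'
#' The configuration must name `ligand_pdb`, `complex_a_pdb`,
#' `complex_b_pdb`, `map_a`, `map_b`, and the ligand atom-name
#' partition `warhead_fixed` / `warhead_mobile` / `linker`.
#'
#' @param config configuration list (see [read_run_config]).
#' @return the `ternary_screen` tibble, invisibly; outputs on disk.
#' @export
run_scan <- function(config) {
  cfg <- utils::modifyList(default_run_config(), config)
  for (key in c("ligand_pdb", "complex_a_pdb", "complex_b_pdb",
                "map_a", "map_b")) {
    if (is.null(cfg[[key]])) abort(sprintf("config lacks '%s'", key))
    if (!file.exists(cfg[[key]])) {
      abort(sprintf("input file for '%s' not found: %s", key, cfg[[key]]))
    }
  }
  ligand <- load_ligand_from_config(cfg)
  conformers <- enumerate_conformers(ligand, cfg$step_deg)
  screen <- screen_conformers(conformers,
                              read_pdb(cfg$complex_a_pdb),
                              read_atom_map(cfg$map_a),
                              read_pdb(cfg$complex_b_pdb),
                              read_atom_map(cfg$map_b),
                              cutoff = cfg$clash_cutoff,
                              max_heavy = cfg$max_heavy,
                              include_ligand = cfg$include_ligand,
                              selection_a = cfg$selection_a,
                              selection_b = cfg$selection_b)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as_tibble(screen),
                   file.path(cfg$out_dir, "viability.csv"),
                   row.names = FALSE)
  if (any(screen$viable)) {
    keep <- which(screen$viable)
    write_multimodel_pdb(conformers$conformers[keep],
                         file.path(cfg$out_dir, "viable_poses.pdb"),
                         remarks = sprintf("REMARK 250 DIHEDRAL_DEG %g",
                                           screen$angle[keep]))
  }
  write_report(list(n_total = nrow(screen), n_viable = sum(screen$viable),
                    viable_angles = screen$angle[screen$viable],
                    parameters = list(step_deg = cfg$step_deg,
                                      clash_cutoff = cfg$clash_cutoff,
                                      max_heavy = cfg$max_heavy,
                                      include_ligand = cfg$include_ligand,
                                      selection_a = cfg$selection_a,
                                      selection_b = cfg$selection_b)),
               cfg, file.path(cfg$out_dir, "scan_summary.json"))
  invisible(screen)
}

#' Select and emit the representative trajectory frame
#'
#' Applies the equilibration filter, selects the lowest-median-RMSD
#' frame, and writes `representative.pdb` plus `represent_report.json`.
#'
#' @param config configuration list; must name `trajectory_pdb`.
#' @param trajectory_pdb optional path overriding the config entry.
#' @return the `representative_frame`, invisibly.
#' @export
run_represent <- function(config, trajectory_pdb = NULL) {
  cfg <- utils::modifyList(default_run_config(), config)
  path <- trajectory_pdb %||% cfg$trajectory_pdb
  if (is.null(path)) abort("config lacks 'trajectory_pdb'")
  traj <- read_trajectory_pdb(path)
  kept <- withCallingHandlers(
    equilibration_filter(traj, cfg$discard_ns),
    warning = function(w) invokeRestart("muffleWarning"))
  if (length(kept) == 0) {
    abort(sprintf(
      "no frames remain after discarding the first %g ns; lower 'discard_ns'",
      cfg$discard_ns))
  }
  if (length(kept) == 1) {
    warn("only one frame remains after equilibration; returning it")
  }
  rep <- select_representative(kept, cfg$align_selection, cfg$rmsd_selection)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_pdb(kept$frames[[rep$index]],
            file.path(cfg$out_dir, "representative.pdb"))
  write_report(list(frame_index = rep$index, time_ns = rep$time_ns,
                    median_rmsd = rep$median_rmsd,
                    n_frames_used = length(kept),
                    discard_ns = cfg$discard_ns,
                    align_selection = cfg$align_selection,
                    rmsd_selection = cfg$rmsd_selection),
               cfg, file.path(cfg$out_dir, "represent_report.json"))
  invisible(rep)
}

#' SPR simulation, fitting, and cooperativity
#'
#' `mode = "simulate"` writes a noisy multi-cycle dataset
#' (`sensorgrams.tsv`) from the configured truth parameters;
#' `mode = "fit"` globally fits a sensorgram table and writes fitted
#' parameters with derived K_D and t_1/2; `mode = "cooperativity"`
#' consumes `kd_binary` / `kd_ternary` from the config and writes
#' alpha with its classification. Each mode writes `spr_<mode>.json`.
#'
#' @param config configuration list.
#' @param mode one of `"simulate"`, `"fit"`, `"cooperativity"`.
#' @param sensorgrams_path input table for `mode = "fit"` (defaults to
#'   `config$sensorgrams`).
#' @return the mode's main result, invisibly.
#' @export
run_spr <- function(config, mode = c("simulate", "fit", "cooperativity"),
                    sensorgrams_path = NULL) {
  mode <- match.arg(mode)
  cfg <- utils::modifyList(default_run_config(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (mode == "simulate") {
    s <- cfg$spr
    series <- injection_series(dilution_series(s$top, s$fold, s$n_points),
                               s$contact_time, s$dissociation_time)
    data <- make_sensorgram_dataset(kinetic_params(s$k_on, s$k_off, s$rmax),
                                    series, noise_sd = s$noise_sd,
                                    seed = cfg$seed)
    write_sensorgrams(data, file.path(cfg$out_dir, "sensorgrams.tsv"))
    write_report(list(n_cycles = length(series$concentrations),
                      concentrations_M = series$concentrations,
                      truth = list(k_on = s$k_on, k_off = s$k_off,
                                   rmax = s$rmax),
                      noise_sd = s$noise_sd),
                 cfg, file.path(cfg$out_dir, "spr_simulate.json"))
    return(invisible(data))
  }
  if (mode == "fit") {
    path <- sensorgrams_path %||% cfg$sensorgrams
    if (is.null(path)) abort("config lacks 'sensorgrams'")
    data <- read_sensorgrams(path)
    fit <- fit_kinetics(data, contact_time = cfg$spr$contact_time)
    g <- glance(fit)
    write_report(list(k_on = g$k_on, k_off = g$k_off, rmax = g$rmax,
                      K_D = g$K_D, t_half = g$t_half,
                      residual_norm = g$residual_norm,
                      n_obs = g$n_obs, n_cycles = g$n_cycles),
                 cfg, file.path(cfg$out_dir, "spr_fit.json"))
    return(invisible(fit))
  }
  if (is.null(cfg$kd_binary) || is.null(cfg$kd_ternary)) {
    abort("cooperativity mode needs 'kd_binary' and 'kd_ternary' in the config")
  }
  coop <- cooperativity(cfg$kd_binary, cfg$kd_ternary)
  write_report(as.list(as_tibble(coop)), cfg,
               file.path(cfg$out_dir, "spr_cooperativity.json"))
  invisible(coop)
}
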