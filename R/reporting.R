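#' Load and validate a run configuration
#'
#' A declarative YAML file drives the report runners.  Recognised keys:
#' `receptor`, `topology` (PDB path), `bw_table` (TSV path),
#' `trajectories` (list of paths), `ligand_resnames`, `thresholds`
#' (`activation_A`, `ionic_lock_A`, `salt_bridge_A`, `contact_A`,
#' `water_A`), `rotation` (`span`), `fes` (`gamma`, `temperature_K`,
#' `hills`, `cv1_range`, `cv2_range`, `n_nodes`), `outdir`, `seed`,
#' `stride`.  Unknown keys are rejected so a typo cannot silently fall
#' back to a default.  Defaults follow the standard monitoring protocol
#' (9.5 / 5 / 4 / 3 / 2 Angstrom cutoffs, gamma = 10, 300 K).
#'
#' @param source path to a YAML file, or a named list.
#' @return Validated config list of class `run_config`.
#' @export
load_run_config <- function(source) {
  cfg <- if (is.character(source)) yaml::read_yaml(source) else source
  known <- c("receptor", "topology", "bw_table", "trajectories",
             "ligand_resnames", "thresholds", "rotation", "fes", "outdir",
             "seed", "stride")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  defaults <- list(
    receptor = NA_character_, ligand_resnames = character(),
    thresholds = list(activation_A = 9.5, ionic_lock_A = 5.0,
                      salt_bridge_A = 4.0, contact_A = 3.0, water_A = 2.0),
    rotation = list(span = "6.44-6.50"),
    fes = list(gamma = 10, temperature_K = 300, cv1_range = c(6, 14),
               cv2_range = c(6, 14), n_nodes = 120),
    outdir = ".", seed = NULL, stride = 1L)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) {
      cfg[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      extra <- setdiff(names(cfg[[nm]]), names(defaults[[nm]]))
      if (nm != "fes" && length(extra) > 0) {
        abort(paste0("unknown config key(s) under ", nm, ": ",
                     paste(extra, collapse = ", ")))
      }
      cfg[[nm]] <- utils::modifyList(defaults[[nm]], cfg[[nm]])
    }
  }
  if (cfg$stride < 1) abort("stride must be >= 1")
  class(cfg) <- "run_config"
  cfg
}

apply_stride <- function(traj, stride) {
  if (stride <= 1L) return(traj)
  keep <- seq(1L, n_frames(traj), by = stride)
  md_trajectory(traj$coords[keep, , , drop = FALSE],
                times = traj$times[keep], replicate = traj$replicate)
}

audit_line <- function(...) {
  message("[microswitchr] ", paste0(...))
}

#' Switch engagement report over replicate trajectories
#'
#' Runs every classified built-in micro-switch over a list of replicate
#' trajectories and writes (when `outdir` is set) one tidy CSV per switch
#' (`time_ps`, `distance_A`, `state`) plus a pooled summary CSV laid out
#' as switches x receptor.  Thresholds and parameters actually used are
#' logged.
#'
#' @param trajectories list of [md_trajectory()] objects (replicates).
#' @param top a [topology_map()].
#' @param receptor receptor label for the summary table.
#' @param definitions switch definitions (default: built-ins).
#' @param stride analyse every `stride`-th frame (default 1: no discard).
#' @param outdir output directory, or `NULL` to skip file output.
#' @return The [engagement_summary()] of all classified switches.
#' @export
run_switch_report <- function(trajectories, top, receptor = NA_character_,
                              definitions = NULL, stride = 1L,
                              outdir = NULL) {
  if (length(trajectories) == 0) abort("no trajectories given")
  if (inherits(trajectories, "md_trajectory")) {
    trajectories <- list(trajectories)
  }
  if (is.null(definitions)) definitions <- builtin_switch_definitions(receptor)
  series <- purrr::map(definitions, function(def) {
    audit_line("switch '", def$name, "': threshold ",
               ifelse(is.na(def$threshold_A), "none (reporter)",
                      paste0(def$threshold_A, " A (", def$engaged_when, ")")),
               ", stride ", stride)
    purrr::map(trajectories, function(tr) {
      switch_series(apply_stride(tr, stride), top, def)
    }) %>% bind_rows()
  }) %>% bind_rows()
  classified <- filter(series, !is.na(.data$engaged))
  summ <- engagement_summary(classified)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in unique(series$switch)) {
      sl <- series[series$switch == nm, ]
      readr::write_csv(
        tibble(time_ps = sl$time_ps, replicate = sl$replicate,
               distance_A = sl$distance_A, state = sl$engaged),
        file.path(outdir, paste0("switch_",
                                 gsub("[^A-Za-z0-9.]+", "_", nm), ".csv")))
    }
    wide <- glance(summ) %>%
      mutate(receptor = receptor) %>%
      select("switch", "receptor", "pct_engaged", "n_frames",
             "n_replicates")
    readr::write_csv(wide, file.path(outdir, "engagement_summary.csv"))
  }
  summ
}

#' Helix-rotation report
#'
#' Measures the rotation of a preset helix-6 span for each trajectory and
#' writes a CSV (`time_ps`, `angle_deg`, `span`) plus a min/max/range
#' summary row.
#'
#' @param trajectories list of [md_trajectory()] objects.
#' @param top a [topology_map()] with reference coordinates (the crystal
#'   structure by convention).
#' @param span a preset name (`"6.44-6.50"`, `"6.44-6.60"`) or a
#'   [helix_span()].
#' @param outdir output directory or `NULL`.
#' @return Tibble of rotation series (all replicates row-bound).
#' @export
run_rotation_report <- function(trajectories, top, span = "6.44-6.50",
                                outdir = NULL) {
  if (inherits(trajectories, "md_trajectory")) {
    trajectories <- list(trajectories)
  }
  if (is.null(top$xyz)) abort("topology carries no reference structure")
  if (is.character(span)) span <- helix6_span(top, span)
  audit_line("rotation span ", span$label, " over ",
             length(trajectories), " trajectories")
  out <- purrr::imap(trajectories, function(tr, i) {
    rotation_series(tr, span, top = top) %>%
      mutate(replicate = tr$replicate)
  }) %>% bind_rows()
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(out, file.path(outdir, "helix_rotation.csv"))
    summ <- out %>%
      group_by(.data$replicate) %>%
      summarise(span = dplyr::first(.data$span),
                min_deg = min(.data$angle_deg),
                max_deg = max(.data$angle_deg),
                range_deg = max(.data$angle_deg) - min(.data$angle_deg),
                .groups = "drop")
    readr::write_csv(summ, file.path(outdir, "helix_rotation_summary.csv"))
  }
  out
}

#' Free-energy surface report from hills files
#'
#' Reads multi-walker hills logs, reconstructs the well-tempered surface,
#' labels the activation-state regions and writes the surface
#' (gnuplot-style text + CSV) and the state summary CSV.  When a topology
#' with reference coordinates is supplied the crystal-structure CV point
#' is evaluated and included.
#'
#' @param hills_paths character vector of hills files (one per walker), or
#'   a ready [hills_log()].
#' @param gamma well-tempered bias factor (required for file input).
#' @param temperature_K temperature.
#' @param cv1_range,cv2_range,n_nodes grid spec (see [reconstruct_fes()]).
#' @param threshold_A activation threshold for region labelling.
#' @param top optional [topology_map()] for the crystal point.
#' @param outdir output directory or `NULL`.
#' @return List: `fes`, `states`, `crystal` (tibble or `NULL`).
#' @export
run_fes_report <- function(hills_paths, gamma = NULL, temperature_K = 300,
                           cv1_range = c(6, 14), cv2_range = c(6, 14),
                           n_nodes = 120, threshold_A = 9.5, top = NULL,
                           outdir = NULL) {
  log <- if (inherits(hills_paths, "hills_log")) hills_paths else {
    if (is.null(gamma)) abort("gamma is required to read hills files")
    read_hills(hills_paths, gamma = gamma, temperature_K = temperature_K)
  }
  audit_line("FES: ", nrow(log), " hills, gamma ", attr(log, "gamma"),
             ", grid ", n_nodes, "^2 over [", cv1_range[1], ",",
             cv1_range[2], "] x [", cv2_range[1], ",", cv2_range[2], "] A")
  fes <- reconstruct_fes(log, cv1_range = cv1_range, cv2_range = cv2_range,
                         n_nodes = n_nodes)
  states <- label_states(fes, threshold_A = threshold_A)
  crystal <- if (!is.null(top)) crystal_point(top) else NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_fes(fes, file.path(outdir, "fes.dat"))
    write_fes(fes, file.path(outdir, "fes.csv"))
    readr::write_csv(states, file.path(outdir, "fes_states.csv"))
    if (!is.null(crystal)) {
      readr::write_csv(crystal, file.path(outdir, "crystal_point.csv"))
    }
  }
  list(fes = fes, states = states, crystal = crystal)
}

#' Write a reproducible synthetic fixture bundle to disk
#'
#' Generates a multi-switch system, a rotating-helix trajectory and a
#' multi-walker hills set, and writes them in the same formats the
#' readers consume (multi-model PDB trajectory, BW TSV, HILLS text) plus
#' a YAML manifest listing every ground-truth parameter.  The same seed
#' always produces an identical bundle.
#'
#' @param outdir destination directory.
#' @param p named engaged fractions for the classified switches.
#' @param n_frames frames for the switch trajectory.
#' @param n_hills_steps Langevin steps per walker for the hills set.
#' @param seed RNG seed.
#' @return Invisibly, a list of the generated objects.
#' @export
write_fixture_bundle <- function(outdir,
                                 p = c("F6.44 activation" = 0.54,
                                       "D3.49-R3.50 salt bridge" = 0.77,
                                       "Ionic lock closure" = 0.73),
                                 n_frames = 2000, n_hills_steps = 400,
                                 seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sw <- gen_microswitch_system(p, n_frames = n_frames, seed = seed)
  write_trajectory(sw$traj, file.path(outdir, "switches.pdb"), top = sw$top)
  write_bw_table(sw$top$bw, file.path(outdir, "bw_table.tsv"))
  rot <- gen_rotating_helix_traj(6 * sin(2 * pi * seq(0, 1, length.out = 60)),
                                 seed = seed)
  write_trajectory(rot$traj, file.path(outdir, "helix.pdb"), top = rot$top)
  met <- run_langevin_metad(potential_double_well(), n_steps = n_hills_steps,
                            seed = seed)
  for (w in sort(unique(met$hills$walker))) {
    write_hills(met$hills, file.path(outdir, sprintf("HILLS.%d", w)),
                walker = w)
  }
  manifest <- list(
    seed = seed,
    switches = list(p = as.list(p), n_frames = n_frames, dwell = 50),
    rotation = list(amplitude_deg = 6, n_frames = 60),
    metadynamics = list(gamma = 10, hill_height_kcal = 0.1,
                        hill_sigma_A = 0.1, pace_ps = 4,
                        n_walkers = length(unique(met$hills$walker)),
                        n_steps = n_hills_steps,
                        barrier_kcal = met$potential$barrier_kcal))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(list(switches = sw, rotation = rot, metad = met))
}
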