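# Configuration-driven end-to-end runs: load trajectory + topology, compute
# every configured metric series, classify states, write tables and a summary.

#' Run the full trajectory analysis
#'
#' Validates the topology against the first frame (aborting with an itemised
#' message before any computation if it does not fit), then computes the
#' aromatic-lid and intracellular-pathway SASA series, the extracellular and
#' intracellular scaffold-bundle distances, every configured gate distance,
#' the ion z-displacement, the TM1a kink angle against the first-frame
#' scaffold axis, and the C-alpha RMSD against the first frame. Writes
#' `metrics.csv` (one row per frame), optionally `states.csv`, a
#' deterministic `summary.json`, and a timestamped `run.log`.
#'
#' @param traj_path Path to a multi-model PDB trajectory.
#' @param topo_path Path to a YAML topology configuration.
#' @param out_dir Output directory (created if needed).
#' @param refs_path Optional path to a reference-point CSV (from
#'   [run_reference()]); enables state classification.
#' @return A list of class `cv_run_report`: output paths, boxplot summaries
#'   per metric, state occupancies (if classified) and provenance.
#' @export
run_analysis <- function(traj_path, topo_path, out_dir, refs_path = NULL) {
  traj <- read_pdb(traj_path)
  topo <- read_topology(topo_path)
  f1 <- get_frame(traj, 1)
  validate_topology(topo, f1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  radii <- default_radii(overrides = topo$sasa$radii,
                         default = topo$sasa$default_radius)
  metrics <- tibble::tibble(frame = seq_len(n_frames(traj)))
  skipped <- character(0)

  if ("lid" %in% names(topo$residue_sets)) {
    rs <- topo$residue_sets$lid
    metrics$lid_sasa_A2 <- sasa_series(
      traj, rs$residues, mode = rs$mode, context = "monomer", radii = radii,
      probe = topo$sasa$probe, n_points = topo$sasa$n_points)$value
  } else skipped <- c(skipped, "lid_sasa_A2: no 'lid' residue set")

  if ("pathway" %in% names(topo$residue_sets)) {
    rs <- topo$residue_sets$pathway
    metrics$pathway_sasa_A2 <- sasa_series(
      traj, rs$residues, mode = rs$mode, context = "monomer", radii = radii,
      probe = topo$sasa$probe, n_points = topo$sasa$n_points)$value
  } else skipped <- c(skipped, "pathway_sasa_A2: no 'pathway' residue set")

  if (!is.null(topo$groups)) {
    metrics$ec_dist_A <- scaffold_bundle_series(traj, topo, "extracellular")$value
    metrics$ic_dist_A <- scaffold_bundle_series(traj, topo, "intracellular")$value
  } else skipped <- c(skipped, "ec_dist_A/ic_dist_A: no groups configured")

  for (g in topo$gates) {
    metrics[[paste0("gate_", gsub("[^A-Za-z0-9]+", "_", g$label), "_A")]] <-
      gate_distance_series(traj, g)$value
  }

  if (!is.null(topo$ion)) {
    align <- selection(chain = topo$chains, class = "CA_ONLY")
    metrics$ion_dz_A <- ion_z_displacement(traj, topo$ion, align,
                                           topo$membrane_normal)$value
  } else skipped <- c(skipped, "ion_dz_A: no ion selection")

  if ("TM1a" %in% topo$helices$tm && !is.null(topo$groups)) {
    h <- topo$helices[topo$helices$tm == "TM1a", ]
    seg <- selection(chain = h$chain, resno = h$first:h$last, class = "CA_ONLY")
    ref_axis <- scaffold_axis(f1, topo)
    metrics$tm1a_kink_deg <- vapply(seq_len(n_frames(traj)), function(k) {
      kink_angle(get_frame(traj, k), seg, ref_axis)
    }, numeric(1))
  } else skipped <- c(skipped, "tm1a_kink_deg: no TM1a helix defined")

  ca_sel <- selection(chain = topo$chains, class = "CA_ONLY")
  metrics$rmsd_A <- rmsd_series(traj, align_sel = ca_sel,
                                measure_sel = ca_sel)$value

  metrics_path <- file.path(out_dir, "metrics.csv")
  readr::write_csv(metrics, metrics_path)

  states <- NULL; states_path <- NULL; occupancy <- NULL
  if (!is.null(refs_path)) {
    refs <- read_reference_points(refs_path)
    states <- classify_trajectory(traj, topo, refs)
    states_path <- file.path(out_dir, "states.csv")
    out <- tidy(states)
    names(out) <- c("frame", "sasa_A2", "ic_dist_A", "label")
    readr::write_csv(out, states_path)
    occupancy <- states$occupancy
  } else skipped <- c(skipped, "states: no references supplied")

  box <- lapply(metrics[setdiff(names(metrics), "frame")], boxplot_stats)
  provenance <- list(tool = "transportcv",
                     version = as.character(utils::packageVersion("transportcv")),
                     config_hash = rlang::hash(topo),
                     n_frames = n_frames(traj), n_atoms = n_atoms(traj))
  summary <- list(
    provenance = provenance,
    boxplots = lapply(box, as.list),
    occupancy = if (is.null(occupancy)) NULL else
      as.list(setNames(occupancy$fraction, occupancy$label)),
    skipped = as.list(skipped)
  )
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")

  log_path <- file.path(out_dir, "run.log")
  writeLines(c(paste0("transportcv ", provenance$version, " run at ",
                      format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
               paste0("trajectory: ", traj_path),
               paste0("topology:   ", topo_path),
               paste0("config hash: ", provenance$config_hash),
               paste0("frames: ", provenance$n_frames,
                      "  atoms: ", provenance$n_atoms),
               if (length(skipped)) paste0("skipped: ", skipped) else
                 "all configured metrics produced",
               "", "topology echo:", yaml::as.yaml(list(
                 chains = topo$chains, membrane_normal = topo$membrane_normal,
                 sasa = topo$sasa, offsets = topo$offsets))),
             log_path)

  structure(list(paths = list(metrics = metrics_path, states = states_path,
                              summary = summary_path, log = log_path),
                 metrics = metrics, boxplots = box, states = states,
                 occupancy = occupancy, skipped = skipped,
                 provenance = provenance),
            class = "cv_run_report")
}

#' @export
print.cv_run_report <- function(x, ...) {
  cat("<cv_run_report> ", x$provenance$n_frames, " frames analysed; outputs:\n",
      sep = "")
  for (p in x$paths) if (!is.null(p)) cat("  ", p, "\n", sep = "")
  invisible(x)
}

#' Emit a synthetic trajectory to disk
#'
#' Writes the multi-model PDB (with HELIX records naming the toy's helix
#' segments), the matching YAML topology and the ground-truth CSV.
#'
#' @param params A `synthetic_params`.
#' @param out_dir Output directory (created if needed).
#' @return Named list of file paths (`trajectory`, `topology`,
#'   `ground_truth`).
#' @export
run_synth <- function(params, out_dir) {
  stopifnot(inherits(params, "synthetic_params"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_trajectory(params)
  paths <- list(trajectory = file.path(out_dir, "synthetic_trajectory.pdb"),
                topology = file.path(out_dir, "synthetic_topology.yaml"),
                ground_truth = file.path(out_dir, "synthetic_ground_truth.csv"))
  hdr <- c(sprintf("REMARK   6 SYNTHETIC TOY TRANSPORTER (transportcv), SEED %d, SCHEDULE %s",
                   params$seed, toupper(params$schedule)),
           format_helix_records(toy_helix_table(params)))
  write_pdb(gen$trajectory, paths$trajectory, header_lines = hdr)
  write_topology(gen$topology, paths$topology)
  readr::write_csv(gen$ground_truth, paths$ground_truth)
  paths
}

#' Compute and save reference points from structure files
#'
#' Reads each reference structure (first model), computes its conformational
#' coordinate under its topology, and writes the labelled reference points as
#' CSV.
#'
#' @param structure_paths Character vector of PDB paths.
#' @param labels State labels, one per structure (must be unique).
#' @param topo_paths YAML topology path(s); a single path is recycled.
#' @param out_path Output CSV path.
#' @return The reference tibble, invisibly written to `out_path`.
#' @export
run_reference <- function(structure_paths, labels, topo_paths, out_path) {
  if (length(labels) != length(structure_paths)) {
    abort("need one label per structure")
  }
  if (anyDuplicated(labels)) abort("duplicate reference labels")
  if (length(topo_paths) == 1) {
    topo_paths <- rep(topo_paths, length(structure_paths))
  }
  structures <- lapply(seq_along(structure_paths), function(i) {
    traj <- read_pdb(structure_paths[i])
    topo <- read_topology(topo_paths[i])
    fr <- get_frame(traj, 1)
    validate_topology(topo, fr)
    list(label = labels[i], frame = fr, topo = topo,
         source = basename(structure_paths[i]))
  })
  refs <- reference_points(structures)
  readr::write_csv(refs, out_path)
  refs
}

#' Read a reference-point CSV
#' @param path CSV written by [run_reference()].
#' @return Reference tibble.
#' @export
read_reference_points <- function(path) {
  refs <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("label", "pathway_sasa_A2", "ic_distance_A")
  if (!all(need %in% names(refs))) {
    abort(paste0("reference file lacks column(s): ",
                 paste(setdiff(need, names(refs)), collapse = ", ")))
  }
  refs
}
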