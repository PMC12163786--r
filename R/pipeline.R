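# Configuration-driven orchestration: load variants and replicas,
# concatenate, run every analysis stage, and emit cross-variant tables
# plus a machine-readable run manifest.

.default_params <- function() list(
  salt_bridge_cutoff_nm = 0.4,
  hbond_cutoff_nm = 0.35,
  hbond_angle_deg = 30,
  hydrophobic_cutoff_nm = 0.45,
  pocket_box_edge_nm = 1.5,
  pocket_spacing_nm = 0.1,
  pocket_stride_ns = 1,
  angle_threshold_deg = 50,
  occupancy_threshold = 0.15,
  histogram_bin_deg = 2.5,
  equilibration_trim_ns = 0,
  frame_interval_ns = 1
)

#' Load a pipeline run configuration
#'
#' Reads a hierarchical key-value (YAML) configuration, or normalizes an
#' equivalent in-memory list. The configuration names the variants (label,
#' conformation, topology path, trajectory paths) and may override any
#' analysis parameter; unstated parameters take the documented defaults
#' (salt-bridge cutoff 0.4 nm, H-bond 0.35 nm / 30 degrees, hydrophobic
#' 0.45 nm, pocket box 1.5 nm at 0.1 nm spacing strided at 1 ns,
#' angle threshold 50 degrees, occupancy filter 0.15, histogram bin
#' 2.5 degrees, equilibration trim 0 ns).
#'
#' @param config path to a YAML file, or a list with elements `variants`
#'   and optionally `params`, `output_dir`, `seed`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$variants))
  labels <- vapply(config$variants, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("variant labels must be unique: ",
         paste(labels[duplicated(labels)], collapse = ", "))
  for (v in config$variants) {
    stopifnot(!is.null(v$topology), !is.null(v$trajectories))
    missing <- c(v$topology, unlist(v$trajectories))
    missing <- missing[!file.exists(missing)]
    if (length(missing))
      stop("missing input file(s) for variant '", v$label, "': ",
           paste(missing, collapse = ", "))
  }
  params <- utils::modifyList(.default_params(),
                              if (is.null(config$params)) list()
                              else config$params)
  structure(list(variants = config$variants, params = params,
                 output_dir = if (is.null(config$output_dir)) "kinaconf-out"
                              else config$output_dir,
                 seed = if (is.null(config$seed)) 1L
                        else as.integer(config$seed)),
            class = "run_config")
}

.write_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  path
}

# analysis stages for one variant's concatenated trajectory
.variant_stages <- function(traj, label, params, motifs, out) {
  p <- params
  sbc <- salt_bridge_criteria(cutoff = p$salt_bridge_cutoff_nm)
  hbc <- hbond_criteria(cutoff = p$hbond_cutoff_nm,
                        angle_cutoff = p$hbond_angle_deg)
  gspec <- pocket_grid_spec(center = motifs$pocket_center,
                            box_edge = p$pocket_box_edge_nm,
                            spacing = p$pocket_spacing_nm)
  angles <- dfg_rotation_angle(traj, motifs, variant_label = label)
  cls <- classify_state(angles, threshold_deg = p$angle_threshold_deg,
                        mode_bin_width = p$histogram_bin_deg)
  hist <- angle_histogram(angles, bin_width = p$histogram_bin_deg)
  vols <- pocket_volume_series(traj, gspec, stride = p$pocket_stride_ns,
                               variant_label = label)
  joint <- joint_angle_volume(angles, vols)
  sb <- interaction_occupancy(
    traj, function(m, xyz) salt_bridge_contacts(m, xyz, sbc), label)
  hb <- interaction_occupancy(
    traj, function(m, xyz) hbond_contacts(m, xyz, hbc, motifs), label)
  hp <- interaction_occupancy(
    traj, function(m, xyz)
      hydrophobic_contacts(m, xyz, motifs, p$hydrophobic_cutoff_nm), label)
  .write_csv(data.frame(frame_time_ns = angles$frame_times,
                        angle_deg = angles$values,
                        label = as.character(cls$labels)),
             file.path(out, paste0(label, "-angle.csv")))
  .write_csv(cls$summary, file.path(out, paste0(label, "-summary.csv")))
  .write_csv(hist, file.path(out, paste0(label, "-angle-histogram.csv")))
  .write_csv(data.frame(frame_time_ns = vols$frame_times,
                        volume_nm3 = vols$values),
             file.path(out, paste0(label, "-pocket-volume.csv")))
  .write_csv(joint, file.path(out, paste0(label, "-joint-angle-volume.csv")))
  .write_csv(as.data.frame(sb),
             file.path(out, paste0(label, "-salt-bridges.csv")))
  .write_csv(as.data.frame(hb), file.path(out, paste0(label, "-hbonds.csv")))
  .write_csv(as.data.frame(hp),
             file.path(out, paste0(label, "-hydrophobic.csv")))
  list(angles = angles, classification = cls, volumes = vols,
       joint = joint, salt_bridges = sb, hbonds = hb, hydrophobic = hp)
}

#' Run the full analysis pipeline
#'
#' For every variant: reads the topology and replica trajectories, trims
#' the configured equilibration window, concatenates the replicas, and
#' computes the DFG angle series with classification and histogram, the
#' salt-bridge / H-bond / hydrophobic occupancy tables, the pocket-volume
#' series and the joint angle-volume table, writing one CSV per result.
#' Across variants it writes the filtered salt-bridge occupancy matrix,
#' the H-bond radar table, and the per-variant summary, plus a JSON run
#' manifest recording the configuration hash, package version, seed and
#' any stage failures. Independent stages continue past a failed one.
#'
#' @param config a `run_config`, or anything [run_config()] accepts.
#' @param motifs a [kinase_motif_map].
#' @return Invisibly, a list of per-variant stage results plus
#'   cross-variant tables and the manifest; `$n_failed` counts failed
#'   stages.
#' @export
run_analysis <- function(config, motifs = kinase_motif_map()) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  failures <- list()
  results <- list()
  for (v in cfg$variants) {
    res <- tryCatch({
      reps <- lapply(unlist(v$trajectories), function(p)
        read_trajectory(read_structure(v$topology), p,
                        frame_interval = cfg$params$frame_interval_ns,
                        replica_id = basename(p)))
      trim <- cfg$params$equilibration_trim_ns
      if (trim > 0)
        reps <- lapply(reps, function(tr) {
          keep <- tr$frame_times - tr$frame_times[1L] >= trim
          trajectory(tr$topology, tr$xyz[keep, , drop = FALSE],
                     tr$frame_times[keep], replica_id = tr$replica_id)
        })
      traj <- concatenate_trajectories(reps)
      .variant_stages(traj, v$label, cfg$params, motifs, out)
    }, error = function(e) {
      failures[[v$label]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) results[[v$label]] <- res
  }
  cross <- tryCatch({
    sb_tables <- lapply(results, `[[`, "salt_bridges")
    hb_tables <- lapply(results, `[[`, "hbonds")
    matrix_tab <- filter_occupancy_matrix(
      unname(sb_tables), threshold = cfg$params$occupancy_threshold)
    radar_tab <- radar_table(unname(hb_tables))
    summary_tab <- do.call(rbind, lapply(results, function(r) {
      s <- r$classification$summary
      js <- attr(r$joint, "summary")
      cbind(s, js[c("volume_mean_nm3", "volume_sd_nm3")])
    }))
    rownames(summary_tab) <- NULL
    .write_csv(matrix_tab, file.path(out, "salt-bridge-matrix.csv"))
    .write_csv(radar_tab, file.path(out, "hbond-radar.csv"))
    .write_csv(summary_tab, file.path(out, "variant-summary.csv"))
    list(matrix = matrix_tab, radar = radar_tab, summary = summary_tab)
  }, error = function(e) {
    failures[["cross-variant"]] <<- conditionMessage(e)
    NULL
  })
  cfg_file <- file.path(out, "config-used.json")
  jsonlite::write_json(list(variants = cfg$variants, params = cfg$params,
                            seed = cfg$seed),
                       cfg_file, auto_unbox = TRUE, pretty = TRUE)
  manifest <- list(
    package = "kinaconf",
    version = as.character(utils::packageVersion("kinaconf")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    variants = vapply(cfg$variants, `[[`, "", "label"),
    failed_stages = failures)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(results, list(cross_variant = cross,
                            manifest = manifest,
                            n_failed = length(failures))))
}

# ---- command-line interface -------------------------------------------

.cli_usage <- function() {
  cat("usage: kinaconf <run|angle|pocket|contacts|synth> [options]\n\n",
      "subcommands:\n",
      "  run       --config <yaml> [--out DIR] [--seed N]\n",
      "            full pipeline from a configuration file\n",
      "  angle     --topology <pdb> --traj <pdb|dcd> [--out FILE]\n",
      "            DFG rotation-angle series (threshold 50 deg,\n",
      "            triple 1980-1997-2103 CA, vertex 1997)\n",
      "  pocket    --topology <pdb> --traj <pdb|dcd> [--out FILE]\n",
      "            grid pocket volume (1.5 nm box, 0.1 nm spacing,\n",
      "            center 2026 CA, 1 ns stride, Bondi radii)\n",
      "  contacts  --topology <pdb> --traj <pdb|dcd> [--out FILE]\n",
      "            salt-bridge occupancy (0.4 nm heavy-atom cutoff)\n",
      "  synth     --preset <dfg-sweep|contacts|cavity> --out DIR\n",
      "            [--seed N]  fixture set + ground-truth sidecar\n\n",
      "common flags: --seed (default 1), --log-level (info|quiet)\n",
      sep = "")
}

.cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("unexpected argument: ", args[i])
    key <- substring(args[i], 3L)
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop("flag --", key, " needs a value")
    flags[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

#' Command-line entry point
#'
#' Dispatcher behind the `inst/scripts/kinaconf.R` Rscript wrapper.
#' Subcommands: `run` (full pipeline from a YAML config), `angle`,
#' `pocket`, `contacts` (single-stage analyses of one trajectory), and
#' `synth` (emit a fixture set with its ground-truth sidecar).
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
kinaconf_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1L] %in% c("-h", "--help", "help")) {
    .cli_usage()
    return(invisible(if (length(args)) 0L else 1L))
  }
  sub <- args[1L]
  status <- tryCatch({
    flags <- .cli_flags(args[-1L])
    seed <- as.integer(if (is.null(flags$seed)) 1L else flags$seed)
    switch(sub,
      run = {
        if (is.null(flags$config)) stop("run needs --config")
        cfg <- run_config(flags$config)
        if (!is.null(flags$out)) cfg$output_dir <- flags$out
        res <- run_analysis(cfg)
        if (res$n_failed > 0) 1L else 0L
      },
      angle = ,
      pocket = ,
      contacts = {
        if (is.null(flags$topology) || is.null(flags$traj))
          stop(sub, " needs --topology and --traj")
        topo <- read_structure(flags$topology)
        traj <- read_trajectory(topo, flags$traj)
        outfile <- if (is.null(flags$out)) stdout() else flags$out
        tab <- switch(sub,
          angle = {
            s <- dfg_rotation_angle(traj)
            data.frame(frame_time_ns = s$frame_times,
                       angle_deg = s$values)
          },
          pocket = {
            s <- pocket_volume_series(traj)
            data.frame(frame_time_ns = s$frame_times,
                       volume_nm3 = s$values)
          },
          contacts = as.data.frame(interaction_occupancy(
            traj, function(m, xyz) salt_bridge_contacts(m, xyz))))
        utils::write.csv(tab, outfile, row.names = FALSE)
        0L
      },
      synth = {
        preset <- if (is.null(flags$preset)) "dfg-sweep" else flags$preset
        outdir <- if (is.null(flags$out)) "kinaconf-fixtures" else flags$out
        tr <- switch(preset,
          "dfg-sweep" = make_dfg_sweep_trajectory(
            sweep_spec(seq(20, 160, by = 10), noise_sd = 2, seed = seed)),
          "contacts" = {
            base <- make_toy_kinase()
            make_contact_schedule_trajectory(
              base,
              list(contact_schedule(atom_selector(1997, "OE1"),
                                    atom_selector(1980, "NZ"),
                                    present_frames = 1:3,
                                    on_distance = 0.35,
                                    off_distance = 0.60)),
              n_frames = 10)
          },
          stop("unknown preset: ", preset))
        write_fixture_set(tr, outdir, stem = preset)
        0L
      },
      {
        .cli_usage()
        1L
      })
  }, error = function(e) {
    message("kinaconf: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(status))
}
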