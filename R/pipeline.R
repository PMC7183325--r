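# End-to-end orchestration: a config-driven pipeline over the analysis
# stages, and a self-contained synthetic demo with planted ground truth.

#' Build a pipeline run configuration
#'
#' @param traj_path trajectory file (PDB multi-model, XYZ or LAMMPS dump).
#' @param topology_path PDB topology file.
#' @param format trajectory format for [read_trajectory()].
#' @param outdir output directory.
#' @param stages character vector from `c("hbonds", "lifetimes",
#'   "dissolution", "twist", "energy")`.
#' @param criteria an [hbond_criteria()].
#' @param threshold dissolution threshold (Angstrom), or `NULL` to
#'   calibrate from `control_path`.
#' @param control_path optional control-trajectory file for threshold
#'   calibration (same format/topology).
#' @param control_timepoints times (ps) for the calibration pool.
#' @param threshold_k standard deviations above the control mean.
#' @param n_tbpcl,n_water solvent composition for wt %% accounting.
#' @param ff_params force-field parameter file path (energy stage), or
#'   `NULL` to use [toy_ff_params()].
#' @param energy_cutoff pair cutoff, Angstrom.
#' @param strand focal (peeling) strand for twist/energy stages.
#' @param lifetime_pairs list of `list(donors=, acceptors=)` name sets for
#'   the lifetimes stage.
#' @param dt,box,timestep_fs passed to [read_trajectory()].
#' @param seed integer seed recorded in the summary.
#' @return object of class `"run_config"` (a validated list).
#' @export
run_config <- function(traj_path, topology_path, format = "pdb-multi-model",
                       outdir = "cellsolv-out",
                       stages = c("hbonds", "dissolution", "twist"),
                       criteria = hbond_criteria(), threshold = NULL,
                       control_path = NULL,
                       control_timepoints = NULL, threshold_k = 4,
                       n_tbpcl = 0, n_water = 0,
                       ff_params = NULL, energy_cutoff = 20, strand = 1L,
                       lifetime_pairs = NULL,
                       dt = 10, box = NULL, timestep_fs = 2, seed = 1L) {
  stages <- match.arg(stages, c("hbonds", "lifetimes", "dissolution",
                                "twist", "energy"), several.ok = TRUE)
  cfg <- list(traj_path = traj_path, topology_path = topology_path,
              format = format, outdir = outdir, stages = stages,
              criteria = criteria, threshold = threshold,
              control_path = control_path,
              control_timepoints = control_timepoints,
              threshold_k = threshold_k, n_tbpcl = n_tbpcl,
              n_water = n_water, ff_params = ff_params,
              energy_cutoff = energy_cutoff, strand = strand,
              lifetime_pairs = lifetime_pairs, dt = dt, box = box,
              timestep_fs = timestep_fs, seed = seed)
  # early validation: every stage's inputs must exist before execution
  for (p in c(traj_path, topology_path)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  if ("dissolution" %in% stages && is.null(threshold) &&
      (is.null(control_path) || is.null(control_timepoints)))
    stop("dissolution stage needs either a threshold or a control ",
         "trajectory with timepoints")
  if (!is.null(control_path) && !file.exists(control_path))
    stop("control trajectory not found: ", control_path)
  if ("energy" %in% stages && !is.null(ff_params) && !file.exists(ff_params))
    stop("force-field parameter file not found: ", ff_params)
  class(cfg) <- "run_config"
  cfg
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order, writing one CSV per stage plus
#' a JSON summary with per-stage provenance.  Deterministic given the
#' config and seed.
#'
#' @param config a [run_config()].
#' @param quiet suppress console log messages (the log file is always
#'   written).
#' @return list of stage results (also written to `config$outdir`),
#'   invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$outdir, "pipeline.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE)
    if (!quiet) message(msg)
  }
  logf("reading topology: ", config$topology_path)
  tf <- read_topology(config$topology_path)
  topo <- tf$topology
  logf("reading trajectory: ", config$traj_path, " (", config$format, ")")
  traj <- read_trajectory(config$traj_path, config$format, topo,
                          dt = config$dt, box = config$box,
                          timestep_fs = config$timestep_fs)
  results <- list()
  summary <- list(package_version = as.character(utils::packageVersion("cellsolv")),
                  seed = config$seed, stages = list())

  for (stage in config$stages) {
    logf("stage: ", stage)
    res <- tryCatch(
      run_stage(stage, traj, config, logf),
      error = function(e) {
        logf("stage ", stage, " FAILED: ", conditionMessage(e))
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e))
      })
    results[[stage]] <- res$data
    if (!is.null(res$csv)) {
      out_csv <- file.path(config$outdir, paste0(stage, ".csv"))
      write.csv(res$csv, out_csv, row.names = FALSE)
      logf("wrote ", out_csv)
    }
    summary$stages[[stage]] <- res$summary
  }
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logf("done")
  invisible(results)
}

run_stage <- function(stage, traj, config, logf) {
  topo <- traj$topology
  switch(stage,
    hbonds = {
      bonds <- detect_hbonds_trajectory(traj, config$criteria)
      cm <- classify_strands(topo$layout %||% default_layout(topo$n_strands))
      avg <- per_glycan_class_average(bonds, topo, cm, traj$times)
      list(data = list(bonds = bonds, averages = avg), csv = avg,
           summary = list(n_bonds = nrow(bonds),
                          n_frames = n_frames(traj)))
    },
    lifetimes = {
      pairs <- config$lifetime_pairs
      if (is.null(pairs))
        pairs <- list(list(donors = c("O2", "O3"), acceptors = c("O5", "O6")))
      rows <- lapply(pairs, function(p) {
        es <- existence_series(traj, p$donors, p$acceptors, config$criteria)
        if (nrow(es$series) == 0L)
          return(data.frame(donors = paste(p$donors, collapse = "+"),
                            acceptors = paste(p$acceptors, collapse = "+"),
                            tau_ps = NA_real_, censored = NA, rendered = "-"))
        res <- lifetime_from_acf(hbond_acf(es$series, es$dt, "continuous"))
        data.frame(donors = paste(p$donors, collapse = "+"),
                   acceptors = paste(p$acceptors, collapse = "+"),
                   tau_ps = res$tau, censored = res$censored,
                   rendered = format_lifetime(res))
      })
      tab <- do.call(rbind, rows)
      list(data = tab, csv = tab, summary = list(n_pairs = nrow(tab)))
    },
    dissolution = {
      thr <- config$threshold
      if (is.null(thr)) {
        ctrl_tf <- read_topology(config$topology_path)
        ctrl <- read_trajectory(config$control_path, config$format,
                                ctrl_tf$topology, dt = config$dt,
                                box = config$box,
                                timestep_fs = config$timestep_fs)
        thr <- calibrate_threshold(ctrl, config$control_timepoints,
                                   config$threshold_k)
        logf("calibrated threshold: ", round(thr$threshold, 3), " A")
      }
      rep <- dissolution_report(traj, thr, config$n_tbpcl, config$n_water)
      rate <- if (nrow(rep) >= 3L && diff(range(rep$wt_pct)) > 0)
        dissolution_rate(rep$time, rep$wt_pct)$slope_per_ns else NA_real_
      list(data = list(report = rep, threshold = thr, rate = rate),
           csv = rep,
           summary = list(threshold_A = if (inherits(thr, "threshold_calibration"))
             thr$threshold else thr, rate_wtpct_per_ns = rate))
    },
    twist = {
      tp <- twist_profile(traj, config$strand)
      list(data = tp, csv = tp,
           summary = list(strand = config$strand,
                          n_junctions = length(unique(tp$junction))))
    },
    energy = {
      params <- if (is.null(config$ff_params)) toy_ff_params()
      else read_ff_params(config$ff_params)
      tr <- energy_trace(traj, params, config$strand,
                         cutoff = config$energy_cutoff)
      list(data = tr, csv = tr,
           summary = list(strand = config$strand,
                          cutoff_A = config$energy_cutoff))
    },
    stop("unknown stage: ", stage))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a miniature end-to-end synthetic demo
#'
#' Builds an 18-strand, 12-glycan bundle, packs a down-scaled solvent box
#' at the 63.1 mol %% water composition ratio, simulates a kinematic peel of
#' one first-layer strand, writes the topology and trajectory to `outdir`
#' together with a ready-to-run [run_config()], and records the planted
#' ground truth in a JSON sidecar.
#'
#' @param outdir writable output directory.
#' @param seed integer seed.
#' @param n_frames trajectory length (default 25 frames at 10 ps).
#' @param displacement final displacement of the peeled strand, Angstrom.
#' @param sigma thermal-noise sd, Angstrom.
#' @return list(config, peeled_strand, truth_path), invisibly.
#' @export
make_demo <- function(outdir, seed = 1L, n_frames = 25L, displacement = 12,
                      sigma = 0.1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  bundle <- build_ibeta_bundle(18L, 12L)
  # 38 TBPCl : 65 water rounds to 63.1 mol % water, the densest mixture
  n_tbpcl <- 38L; n_water <- 65L
  packed <- pack_solvent(list(n_tbpcl = n_tbpcl, n_water = n_water),
                         box = bundle$frame$box, bundle = bundle,
                         seed = seed)
  cm <- classify_strands(bundle$topology$layout)
  # a mid-row first-layer strand: its sheet neighbours keep other partners,
  # so only the planted strand's glycans cross the threshold
  mid <- cm$class == "first_layer" &
    cm$col > min(cm$col) + 1 & cm$col < max(cm$col) - 1
  peel_strand <- cm$strand[mid][1]
  plan <- peel_plan(peel_strand,
                    displacement = seq(0, displacement, length.out = n_frames),
                    twist = seq(0, 10, length.out = n_frames),
                    sigma = sigma, profile = "uniform", seed = seed)
  traj <- generate_peeling_trajectory(packed$topology, packed$frame, plan,
                                      n_frames, dt = 10)
  topo_path <- file.path(outdir, "demo_topology.pdb")
  traj_path <- file.path(outdir, "demo_trajectory.pdb")
  write_pdb(packed$topology, packed$frame, topo_path)
  write_pdb(packed$topology, traj$frames, traj_path)
  # static control for threshold calibration (jitter only)
  ctrl_plan <- peel_plan(peel_strand, displacement = rep(0, n_frames),
                         sigma = sigma, seed = seed + 1L)
  ctrl <- generate_peeling_trajectory(packed$topology, packed$frame,
                                      ctrl_plan, n_frames, dt = 10)
  ctrl_path <- file.path(outdir, "demo_control.pdb")
  write_pdb(packed$topology, ctrl$frames, ctrl_path)

  truth <- list(seed = seed, peeled_strand = peel_strand,
                displacement_A = displacement,
                mol_pct_water = round(mol_percent_water(n_water, n_tbpcl), 1),
                n_tbpcl = n_tbpcl, n_water = n_water,
                n_deleted = as.list(packed$n_deleted))
  truth_path <- file.path(outdir, "demo_truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)

  cfg <- run_config(
    traj_path = traj_path, topology_path = topo_path,
    format = "pdb-multi-model", outdir = file.path(outdir, "results"),
    stages = c("hbonds", "dissolution", "twist"),
    control_path = ctrl_path,
    control_timepoints = ctrl$times[c(2, n_frames %/% 2, n_frames)],
    n_tbpcl = n_tbpcl, n_water = n_water, strand = peel_strand,
    dt = 10, seed = seed)
  invisible(list(config = cfg, peeled_strand = peel_strand,
                 truth_path = truth_path))
}
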