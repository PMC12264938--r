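#' Workflow configuration
#'
#' The pose-ranking workflow runs in four stages — `prepare` (equilibrium
#' statistics and restraint selection), `flatten` (adaptive bias
#' optimization), `run` (replica lambda-dynamics production) and `estimate`
#' (reference-state corrections and cycle assembly) — driven by one
#' configuration with a single top-level seed from which every stage seed is
#' derived deterministically. Exactly one restraint scheme is active per
#' run: `"multiple_distance"` (protein-ligand flat-bottom restraints
#' selected from trajectory statistics) or `"inter_pose"` (stiff tethers
#' between corresponding atoms of the two poses).
#'
#' `default_workflow_config()` returns the full default configuration;
#' `read_workflow_config()` reads a TOML-style `key = value` file with
#' `[section]` headers and `#` comments, overlaying the defaults.
#'
#' @param outdir Output directory.
#' @param seed Top-level integer seed.
#' @return A nested configuration list.
#' @export
default_workflow_config <- function(outdir = "lambdapose-run", seed = 1L) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    system = list(kind = "asymmetric", temperature = DEFAULT_TEMPERATURE),
    restraints = list(scheme = "multiple_distance", k = 40,
                      band_lo = 10, band_hi = 15, half_width = 4,
                      tether_k = 100, tether_width = 2),
    sampling = list(dt = 0.002, stride = 10, coord_stride = 100,
                    equilibrium_steps = 60000,
                    flatten_iterations = 12, flatten_steps = 40000,
                    production_steps = 120000, n_replicas = 5,
                    discard_fraction = 1 / 6,
                    reference_steps = 90000, reference_replicas = 3),
    estimate = list(threshold = 0.99, n_boot = 1000,
                    components_file = NULL)
  )
}

#' @rdname default_workflow_config
#' @param path Path to a config file.
#' @export
read_workflow_config <- function(path) {
  cfg <- default_workflow_config()
  lines <- readLines(path)
  section <- NULL
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("\\[|\\]", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("cannot parse config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    val <- gsub('^"|"$', "", val)
    parsed <- if (val %in% c("true", "false")) as.logical(toupper(val))
              else if (grepl("^-?[0-9.eE+/-]+$", val) &&
                       !is.na(suppressWarnings(as.numeric(val))))
                as.numeric(val)
              else val
    if (is.null(section)) cfg[[key]] <- parsed
    else cfg[[section]][[key]] <- parsed
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname default_workflow_config
#' @param cfg A configuration list.
#' @export
show_config <- function(cfg = default_workflow_config()) {
  emit <- function(x, prefix = NULL) {
    for (nm in names(x)) {
      v <- x[[nm]]
      if (is.list(v)) {
        cat("[", nm, "]\n", sep = "")
        emit(v)
      } else if (!is.null(v)) {
        cat(nm, " = ", format(v), "\n", sep = "")
      }
    }
  }
  top <- cfg[!vapply(cfg, is.list, logical(1))]
  emit(top)
  emit(cfg[vapply(cfg, is.list, logical(1))])
  invisible(cfg)
}

workflow_system <- function(cfg) {
  kind <- cfg$system$kind
  spec <- switch(kind,
    symmetric = toy_spec_symmetric(cfg$system$temperature, cfg$seed),
    asymmetric = toy_spec_asymmetric(cfg$system$temperature, cfg$seed),
    barrier = toy_spec_barrier(cfg$system$temperature, cfg$seed),
    if (file.exists(kind)) return(read_system_json(kind))
    else stop("unknown system kind or missing file: ", kind))
  make_dual_pose_toy(spec)
}

stage_log <- function(stage, t0, ...) {
  msg <- paste(..., collapse = " ")
  message(sprintf("[%s] %.1fs %s", stage,
                  as.numeric(Sys.time()) - t0, msg))
}

sim_cfg_for <- function(cfg, n_steps, seed_offset) {
  simulation_config(dt = cfg$sampling$dt, n_steps = n_steps,
                    temperature = cfg$system$temperature,
                    lambda_save_stride = cfg$sampling$stride,
                    coord_save_stride = cfg$sampling$coord_stride,
                    seed = derive_seed(cfg$seed, seed_offset))
}

#' Workflow stages
#'
#' @param cfg A configuration list ([default_workflow_config()]) or the
#'   path to a config file.
#' @return Each stage invisibly returns its main products and writes its
#'   files under `cfg$outdir`; see Details.
#'
#' @details
#' `cmd_prepare()` builds the toy system, runs per-pose equilibrium sampling
#' at the corresponding alchemical end state, computes ligand-protein pair
#' statistics, selects the restraints for the configured scheme and writes
#' `system.json`, `pair_stats.csv`, `restraints.txt` and an equilibrium XYZ
#' trajectory per pose.
#'
#' `cmd_flatten()` optimizes a tabulated flattening bias and writes
#' `bias.json` plus `flatten_diagnostics.csv`; its return carries the
#' `flattened` flag (a not-flattened outcome is a warning, not an error).
#'
#' `cmd_run()` runs the replica production protocol with the saved bias and
#' writes one lambda-trace file per replica plus `run_diagnostics.json`
#' (transitions per ns, physical-ligand fraction).
#'
#' `cmd_estimate()` computes the restrained core free energy from the
#' traces, samples the reference state for the two one-step restraint
#' corrections, assembles the thermodynamic cycle and writes
#' `cycle_report.json` (components, combined value, uncertainties,
#' diagnostics, provenance) and `cycle_report.csv`. When
#' `estimate$components_file` points to a JSON file with pre-computed
#' components, only the cycle combination is performed.
#'
#' `cmd_all()` chains the four stages.
#' @export
cmd_prepare <- function(cfg) {
  cfg <- as_workflow_config(cfg)
  t0 <- as.numeric(Sys.time())
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  system <- workflow_system(cfg)
  write_system_json(system, file.path(cfg$outdir, "system.json"))
  n_env <- nrow(system$env_coords)
  n1 <- nrow(system$poses[[1]]$coords)
  n2 <- nrow(system$poses[[2]]$coords)
  scheme <- cfg$restraints$scheme
  stats_all <- list()
  if (scheme == "multiple_distance") {
    sets <- list()
    for (p in 1:2) {
      scfg <- sim_cfg_for(cfg, cfg$sampling$equilibrium_steps, 10 + p)
      lam_fix <- if (p == 1) c(1, 0) else c(0, 1)
      run <- run_lambda_dynamics(system, NULL, NULL, scfg,
                                 fixed_lambda = lam_fix)
      frames_global <- lapply(run$frames, function(fr) {
        rbind(system$env_coords, fr[[1]], fr[[2]])
      })
      lig <- n_env + (if (p == 1) seq_len(n1) else n1 + seq_len(n2))
      st <- compute_pair_stats(frames_global, ligand_atoms = lig,
                               protein_atoms = seq_len(n_env))
      stats_all[[p]] <- dplyr::mutate(st, pose = p)
      sets[[p]] <- select_multiple_distance_restraints(
        st, band = c(cfg$restraints$band_lo, cfg$restraints$band_hi),
        half_width = cfg$restraints$half_width, k = cfg$restraints$k)
      write_xyz(run$frames, system,
                file.path(cfg$outdir, sprintf("equilibrium_pose%d.xyz", p)))
    }
    restraints <- restraint_set(
      kind = c(sets[[1]]$kind, sets[[2]]$kind),
      atom_i = c(sets[[1]]$atom_i, sets[[2]]$atom_i),
      atom_j = c(sets[[1]]$atom_j, sets[[2]]$atom_j),
      r_min = c(sets[[1]]$r_min, sets[[2]]$r_min),
      r_max = c(sets[[1]]$r_max, sets[[2]]$r_max),
      k = c(sets[[1]]$k, sets[[2]]$k))
    utils::write.csv(dplyr::bind_rows(stats_all),
                     file.path(cfg$outdir, "pair_stats.csv"),
                     row.names = FALSE)
  } else if (scheme == "inter_pose") {
    if (n1 != n2) stop("inter-pose tethering needs matching pose atom counts")
    restraints <- build_interpose_tethers(
      pose1_atoms = n_env + seq_len(n1),
      pose2_atoms = n_env + n1 + seq_len(n2),
      k = cfg$restraints$tether_k, width = cfg$restraints$tether_width)
  } else stop("exactly one restraint scheme per run: ",
              "'multiple_distance' or 'inter_pose'")
  write_restraint_table(restraints, file.path(cfg$outdir, "restraints.txt"))
  write_run_manifest(list(seed = cfg$seed, stage = "prepare"),
                     file.path(cfg$outdir, "prepare_manifest.json"))
  stage_log("prepare", t0, nrow(restraints), "restraints selected")
  invisible(list(system = system, restraints = restraints,
                 stats = if (length(stats_all)) dplyr::bind_rows(stats_all)
                         else NULL))
}

as_workflow_config <- function(cfg) {
  if (is.character(cfg)) read_workflow_config(cfg) else cfg
}

load_prepared <- function(cfg) {
  list(system = read_system_json(file.path(cfg$outdir, "system.json")),
       restraints = read_restraint_table(file.path(cfg$outdir,
                                                   "restraints.txt")))
}

#' @rdname cmd_prepare
#' @export
cmd_flatten <- function(cfg) {
  cfg <- as_workflow_config(cfg)
  t0 <- as.numeric(Sys.time())
  pr <- load_prepared(cfg)
  scfg <- sim_cfg_for(cfg, cfg$sampling$flatten_steps, 20)
  bias_path <- file.path(cfg$outdir, "bias.json")
  init_bias <- if (file.exists(bias_path)) read_bias_json(bias_path) else NULL
  res <- flatten_alf(pr$system, pr$restraints, scfg,
                     schedule = list(
                       n_iterations = cfg$sampling$flatten_iterations,
                       steps_per_iteration = cfg$sampling$flatten_steps),
                     init_bias = init_bias)
  write_bias_json(res$bias, file.path(cfg$outdir, "bias.json"))
  utils::write.csv(res$diagnostics,
                   file.path(cfg$outdir, "flatten_diagnostics.csv"),
                   row.names = FALSE)
  if (!res$flattened) {
    warning("lambda landscape not flattened within the schedule; ",
            "best-so-far bias written")
  }
  stage_log("flatten", t0, "flattened =", res$flattened,
            "after", nrow(res$diagnostics), "iterations")
  invisible(res)
}

#' @rdname cmd_prepare
#' @export
cmd_run <- function(cfg) {
  cfg <- as_workflow_config(cfg)
  t0 <- as.numeric(Sys.time())
  pr <- load_prepared(cfg)
  bias <- read_bias_json(file.path(cfg$outdir, "bias.json"))
  scfg <- sim_cfg_for(cfg, cfg$sampling$production_steps, 30)
  traces <- run_replica_protocol(pr$system, bias, pr$restraints, scfg,
                                 n_replicas = cfg$sampling$n_replicas,
                                 discard_fraction =
                                   cfg$sampling$discard_fraction)
  for (i in seq_along(traces)) {
    write_lambda_trace(traces[[i]],
                       file.path(cfg$outdir, sprintf("trace_%d.txt", i)))
  }
  dg <- trace_diagnostics(traces, cfg$estimate$threshold)
  jsonlite::write_json(as.list(dg),
                       file.path(cfg$outdir, "run_diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  write_run_manifest(list(seed = cfg$seed, stage = "run"),
                     file.path(cfg$outdir, "run_manifest.json"))
  stage_log("run", t0, length(traces), "replicas;",
            sprintf("%.1f transitions/ns", dg$transitions_per_ns))
  invisible(traces)
}

#' @rdname cmd_prepare
#' @export
cmd_estimate <- function(cfg) {
  cfg <- as_workflow_config(cfg)
  t0 <- as.numeric(Sys.time())
  comp_file <- cfg$estimate$components_file
  if (!is.null(comp_file) && nzchar(comp_file)) {
    comp <- jsonlite::read_json(comp_file, simplifyVector = TRUE)
    cyc <- combine_cycle(
      free_energy_estimate(comp$osp_add_xray$value,
                           comp$osp_add_xray$uncertainty, "Zwanzig"),
      free_energy_estimate(comp$msld_core$value,
                           comp$msld_core$uncertainty, "WHAM"),
      free_energy_estimate(comp$osp_remove_flip$value,
                           comp$osp_remove_flip$uncertainty, "Zwanzig"))
    diagnostics <- NULL
  } else {
    pr <- load_prepared(cfg)
    bias <- read_bias_json(file.path(cfg$outdir, "bias.json"))
    trace_files <- list.files(cfg$outdir, "^trace_[0-9]+\\.txt$",
                              full.names = TRUE)
    traces <- lapply(trace_files, read_lambda_trace)
    core <- wham_deltaG(traces, bias, cfg$system$temperature,
                        threshold = cfg$estimate$threshold,
                        n_boot = cfg$estimate$n_boot,
                        seed = derive_seed(cfg$seed, 40))
    scfg <- sim_cfg_for(cfg, cfg$sampling$reference_steps, 50)
    ens <- run_reference_state(pr$system, pr$restraints, scfg,
                               n_replicas = cfg$sampling$reference_replicas)
    osp_x <- osp_restraint_correction(ens, "xray",
                                      n_boot = cfg$estimate$n_boot,
                                      seed = derive_seed(cfg$seed, 41))
    osp_f <- osp_restraint_correction(ens, "flip",
                                      n_boot = cfg$estimate$n_boot,
                                      seed = derive_seed(cfg$seed, 42))
    cyc <- combine_cycle(osp_x, core, osp_f)
    diagnostics <- trace_diagnostics(traces, cfg$estimate$threshold)
  }
  report <- list(
    components = lapply(
      list(osp_add_xray = cyc$osp_add_xray, msld_core = cyc$msld_core,
           osp_remove_flip = cyc$osp_remove_flip),
      function(e) list(value = e$value, uncertainty = e$uncertainty,
                       method = e$method)),
    combined = list(value = cyc$combined$value,
                    uncertainty = cyc$combined$uncertainty),
    diagnostics = if (!is.null(diagnostics)) as.list(diagnostics),
    provenance = list(seed = cfg$seed,
                      config_hash = rlang::hash(cfg),
                      package_version =
                        as.character(utils::packageVersion("lambdapose")))
  )
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(cfg$outdir, "cycle_report.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(tidy(cyc), file.path(cfg$outdir, "cycle_report.csv"),
                   row.names = FALSE)
  stage_log("estimate", t0,
            sprintf("DDG(xray->flip) = %.3f +- %.3f kcal/mol",
                    cyc$combined$value, cyc$combined$uncertainty))
  invisible(cyc)
}

#' @rdname cmd_prepare
#' @export
cmd_all <- function(cfg) {
  cfg <- as_workflow_config(cfg)
  cmd_prepare(cfg)
  cmd_flatten(cfg)
  cmd_run(cfg)
  cmd_estimate(cfg)
}
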