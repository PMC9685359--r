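#' Build a pipeline configuration
#'
#' All tunable defaults of the analysis in one place: SASA threshold
#' 50 A^2, contact cutoff 3.5 A, H-bond criterion 3.5 A / 30 deg, SASA
#' probe 1.4 A, CCS probe 1.0 A, tail fraction 0.1, contact binarization
#' threshold 0.5. Where a value has no field-standard default it is a
#' scenario choice documented in the methods vignette.
#'
#' @param ... Named overrides of any default.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    target_charge = 10,
    sasa_threshold = 50,
    sasa_probe = 1.4,
    ccs_probe = 1.0,
    contact_cutoff = 3.5,
    hbond_distance = 3.5,
    hbond_angle = 30,
    tail_fraction = 0.1,
    presence_threshold = 0.5,
    neighbor_mode = "sequence",
    n_orientations = 32,
    selection = "calpha",
    scenario = list(generate = TRUE, n_res_per_chain = 24, n_replicas = 6,
                    n_frames = 30, t_max = 500, s_vacuum = 0.96,
                    s_rehydrated = 0.9875, jitter_sigma = 0.3,
                    loop_boost = 3, persistent_fraction = 0.1),
    inputs = NULL,   # named list bulk/vacuum/rehydration of PDB paths
    output_dir = NULL
  )
  over <- list(...)
  for (nm in names(over)) {
    if (nm == "scenario") {
      cfg$scenario[names(over$scenario)] <- over$scenario
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  out$inputs <- out$inputs
  yaml::write_yaml(out, path)
  invisible(path)
}

load_phase_replicas <- function(paths, topology, phase, dt) {
  trs <- lapply(seq_along(paths), function(i) {
    read_trajectory(paths[[i]], topology, dt = dt,
                    replica_id = paste0(phase, "_r", i), phase = phase)
  })
  replica_set(trs)
}

#' Run the full compaction/recovery analysis pipeline
#'
#' Stages: (1) obtain three phase-labelled replica ensembles (generated
#' from the synthetic scenario, or read from multi-model PDB files); (2)
#' vacuum protonation-site assignment from the bulk ensemble's per-residue
#' SASA; (3) per-frame geometry series (CCS, SASA, volume), tail-window
#' contact occupancy and hydrogen-bond means per phase; (4) the recovery
#' report. Deterministic given the config seed. When an output directory
#' is configured, series CSVs, occupancy TSVs, the protonation plan, the
#' recovery report (JSON) and a run log are written.
#'
#' @param config A `pipeline_config`.
#' @return List with `report` (a `recovery_report`), `plan`
#'   (a `protonation_plan`), `series`, `occupancy`, `hbonds`,
#'   `ground_truth` (synthetic scenarios only) and `files` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "setup"
  files <- character(0)
  outdir <- config$output_dir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  result <- tryCatch({
    stage <- "ensembles"
    gt <- NULL
    if (isTRUE(config$scenario$generate)) {
      sc <- config$scenario
      scen <- default_scenario(
        n_res_per_chain = sc$n_res_per_chain, n_replicas = sc$n_replicas,
        n_frames = sc$n_frames, t_max = sc$t_max, s_vacuum = sc$s_vacuum,
        s_rehydrated = sc$s_rehydrated, jitter_sigma = sc$jitter_sigma,
        loop_boost = sc$loop_boost,
        persistent_fraction = sc$persistent_fraction, seed = config$seed)
      ref <- scen$ref
      ensembles <- lapply(scen$specs, function(sp) {
        generate_phase_ensemble(ref, sp)
      })
      gt <- ground_truth(ref, scen$specs, ccs_probe = config$ccs_probe,
                         sasa_probe = config$sasa_probe,
                         cutoff = config$contact_cutoff)
    } else {
      if (is.null(config$inputs)) abort("config error: no inputs and no scenario")
      ref <- read_structure(config$inputs$topology)
      ref <- assign_solution_charges(ref)
      dt <- config$inputs$dt %||% 1
      ensembles <- list(
        bulk = load_phase_replicas(config$inputs$bulk, ref, "bulk", dt),
        vacuum = load_phase_replicas(config$inputs$vacuum, ref, "vacuum", dt),
        rehydration = load_phase_replicas(config$inputs$rehydration, ref,
                                          "rehydration", dt)
      )
    }
    timings$ensembles <- proc.time()[["elapsed"]] - t0

    stage <- "protonation"
    t1 <- proc.time()[["elapsed"]]
    sasa_tab <- per_residue_sasa(ensembles$bulk, probe = config$sasa_probe,
                                 restrict = CANDIDATE_TYPES,
                                 n_points = 240)
    cand <- select_candidates(sasa_tab, threshold = config$sasa_threshold)
    cand <- apply_neighbor_exclusion(cand, ref, mode = config$neighbor_mode)
    plan <- build_protonation_plan(ref, cand, config$target_charge)
    protonated <- apply_plan(ref, plan)
    timings$protonation <- proc.time()[["elapsed"]] - t1

    stage <- "metrics"
    t1 <- proc.time()[["elapsed"]]
    series <- lapply(ensembles, function(rs) {
      frame_geometry_series(rs, ccs_probe = config$ccs_probe,
                            sasa_probe = config$sasa_probe,
                            n_orientations = config$n_orientations,
                            seed = config$seed)
    })
    nf <- min(vapply(ensembles, function(rs) min(rs$n_frames), integer(1)))
    n_tail <- max(1L, floor(nf * config$tail_fraction))
    window <- seq(nf - n_tail + 1L, nf)
    occupancy <- lapply(ensembles, contact_occupancy, window = window,
                        cutoff = config$contact_cutoff)
    hbonds <- lapply(ensembles, function(rs) {
      h <- hydrogen_bond_mean(rs, window = window,
                              d_cutoff = config$hbond_distance,
                              angle_cutoff = config$hbond_angle)
      as.numeric(h)
    })
    timings$metrics <- proc.time()[["elapsed"]] - t1

    stage <- "recovery"
    report <- recovery_report(series, occupancy, hbonds,
                              tail_fraction = config$tail_fraction,
                              presence_threshold = config$presence_threshold)

    stage <- "output"
    if (!is.null(outdir)) {
      for (ph in names(series)) {
        f <- file.path(outdir, paste0("series_", ph, ".csv"))
        df <- dplyr::bind_rows(lapply(names(series[[ph]]), function(m) {
          s <- series[[ph]][[m]]
          tibble::tibble(metric = m, time_ns = s$time, mean = s$mean,
                         sd = s$spread)
        }))
        utils::write.csv(df, f, row.names = FALSE)
        files <- c(files, f)
        f <- file.path(outdir, paste0("occupancy_", ph, ".tsv"))
        utils::write.table(round(unclass(occupancy[[ph]]), 6), f, sep = "\t",
                           row.names = FALSE, col.names = FALSE)
        files <- c(files, f)
      }
      f <- file.path(outdir, "protonation_plan.json")
      jsonlite::write_json(tidy(plan), f, digits = NA, pretty = TRUE)
      files <- c(files, f)
      f <- file.path(outdir, "recovery_report.json")
      jsonlite::write_json(
        list(summary = report$summary,
             contacts = report$contacts,
             hbond_mean = hbonds,
             tail_fraction = config$tail_fraction),
        f, digits = NA, pretty = TRUE, auto_unbox = TRUE)
      files <- c(files, f)
      if (!is.null(gt)) {
        f <- file.path(outdir, "ground_truth.json")
        jsonlite::write_json(
          list(compaction = gt$compaction, recovery = gt$recovery,
               contact_fractions = gt$contact_fractions,
               scales = as.list(gt$scales)),
          f, digits = NA, pretty = TRUE, auto_unbox = TRUE)
        files <- c(files, f)
      }
      f <- file.path(outdir, "run_log.json")
      cfg_for_hash <- unclass(config)
      cfg_for_hash$output_dir <- NULL
      jsonlite::write_json(
        list(package_version = as.character(utils::packageVersion("vacuform")),
             r_version = R.version.string,
             config = cfg_for_hash,
             config_hash = rlang::hash(cfg_for_hash),
             timings_s = lapply(timings, round, 2)),
        f, pretty = TRUE, auto_unbox = TRUE)
      files <- c(files, f)
    }
    list(report = report, plan = plan, protonated = protonated,
         series = series, occupancy = occupancy, hbonds = hbonds,
         ground_truth = gt, files = files)
  }, error = function(e) {
    abort(paste0("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)))
  })
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a
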