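# File formats and the end-to-end pipeline driver.  Tables travel as CSV
# (with '#' metadata headers) or as an RDS binary container; reports as JSON;
# configurations as YAML.

.TABLE_SCHEMA_VERSION <- 1L

#' Write a mapping table
#'
#' CSV carries unit-annotated columns plus `#`-prefixed metadata lines
#' (schema version, whisker fingerprint, grid, exclusion cone); `.rds`
#' writes the same object as a binary columnar container.
#'
#' @param table a `mapping_table`.
#' @param path output path; format chosen by extension (.csv or .rds).
#' @return `path`, invisibly.
#' @export
write_mapping_table <- function(table, path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    obj <- table
    obj$schema_version <- .TABLE_SCHEMA_VERSION
    saveRDS(obj, path)
    return(invisible(path))
  }
  meta <- list(schema_version = .TABLE_SCHEMA_VERSION,
               whisker_fingerprint = table$whisker_fingerprint,
               cone_deg = table$cone_deg,
               grid_spec = table$grid_spec)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# whiskmap_mapping_table ",
                    jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)),
             con)
  writeLines("# units: r mm, angles deg, F uN, M uN*mm, directions rad", con)
  write.csv(table$records, con, row.names = FALSE)
  invisible(path)
}

#' Read a mapping table written by [write_mapping_table()]
#'
#' @param path .csv or .rds path.
#' @return a `mapping_table`.
#' @export
read_mapping_table <- function(path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    obj <- readRDS(path)
    .assert(!is.null(obj$schema_version), "not a whiskmap mapping table")
    .assert(obj$schema_version <= .TABLE_SCHEMA_VERSION,
            sprintf("table schema version %s is newer than supported (%s)",
                    obj$schema_version, .TABLE_SCHEMA_VERSION))
    obj$schema_version <- NULL
    class(obj) <- "mapping_table"
    return(obj)
  }
  hdr <- readLines(path, n = 1)
  .assert(grepl("^# whiskmap_mapping_table ", hdr),
          "not a whiskmap mapping table file")
  meta <- jsonlite::fromJSON(sub("^# whiskmap_mapping_table ", "", hdr))
  .assert(meta$schema_version <= .TABLE_SCHEMA_VERSION,
          sprintf("table schema version %s is newer than supported (%s)",
                  meta$schema_version, .TABLE_SCHEMA_VERSION))
  rec <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  structure(list(records = rec,
                 grid_spec = meta$grid_spec,
                 whisker_fingerprint = meta$whisker_fingerprint,
                 cone_deg = meta$cone_deg,
                 n_converged = sum(rec$converged),
                 n_discarded = sum(!rec$converged),
                 n_excluded = sum(rec$converged &
                                  rec$excluded_small_deflection)),
            class = "mapping_table")
}

#' Write / read a whisking trajectory as CSV
#'
#' @param traj a `whisk_trajectory`.
#' @param path output path.
#' @return `path` invisibly (write); a data frame of frames (read).
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- list(schema_version = .TABLE_SCHEMA_VERSION,
               whisker_fingerprint = traj$whisker_fingerprint,
               peg = unclass(traj$peg), seed = traj$seed)
  writeLines(paste0("# whiskmap_trajectory ",
                    jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)),
             con)
  writeLines("# units: t ms, positions mm, angles deg; 1 kHz frames", con)
  write.csv(traj$frames, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  hdr <- readLines(path, n = 1)
  .assert(grepl("^# whiskmap_trajectory ", hdr),
          "not a whiskmap trajectory file")
  meta <- jsonlite::fromJSON(sub("^# whiskmap_trajectory ", "", hdr))
  .assert(meta$schema_version <= .TABLE_SCHEMA_VERSION,
          "trajectory schema version is newer than supported")
  fr <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  structure(list(frames = fr, whisker_fingerprint = meta$whisker_fingerprint,
                 peg = do.call(peg_model, meta$peg),
                 seed = meta$seed),
            class = "whisk_trajectory")
}

#' Write a uniqueness census as JSON
#'
#' The report mirrors the region-condition vocabulary (All / ELD / CF / CB)
#' per triplet, with the error metrics and overlap diagnostics of each test.
#'
#' @param census from [uniqueness_census()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_uniqueness_report <- function(census, path) {
  rows <- lapply(census$reports, function(r) {
    list(triplet = paste(r$triplet, collapse = "+"),
         condition = r$condition, verdict = r$verdict,
         n_records = r$n_records,
         err_r_mm = r$err_r_mm, err_theta_deg = r$err_theta_deg,
         err_phi_deg = r$err_phi_deg,
         net_votes = sum(r$net_votes), net_fits = length(r$net_votes),
         overlap_count = r$overlap_count)
  })
  jsonlite::write_json(list(schema_version = .TABLE_SCHEMA_VERSION,
                            condition = census$condition,
                            unique = census$unique, reports = rows),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write binned sensitivity summaries as JSON
#'
#' @param binned a `binned_sensitivity`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_binned_sensitivity <- function(binned, path) {
  out <- list(schema_version = .TABLE_SCHEMA_VERSION,
              n_bins = binned$n_bins,
              steps = as.list(binned$steps),
              interp_method = binned$interp_method,
              elements = lapply(binned$elements, function(e) {
                list(n_valid = e$n_valid, n_trimmed = e$n_trimmed,
                     n_binned = e$n_binned, bins = e$bins)
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Pipeline configuration
#'
#' @param whisker_params list of [build_gamma_like_whisker()] arguments (or
#'   `list(file = "path.csv")` to load a tracked shape).
#' @param grid_params list of [build_grid()] arguments.
#' @param solver list of [solver_options()] arguments.
#' @param uniqueness list: `thresholds` ([uniqueness_thresholds()]
#'   arguments), `seeds`, `condition`.
#' @param sensitivity list: `run` flag, `k`.
#' @param demo list of [synth_whisk_trial()] arguments plus `run` flag.
#' @param seed global seed; stage seeds derive from it as seed + stage
#'   index.
#' @param out_dir output directory.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(whisker_params = list(), grid_params = list(),
                       solver = list(), uniqueness = list(),
                       sensitivity = list(run = TRUE),
                       demo = list(run = TRUE), seed = 1,
                       out_dir = "whiskmap_out") {
  cfg <- list(whisker_params = whisker_params, grid_params = grid_params,
              solver = solver, uniqueness = uniqueness,
              sensitivity = sensitivity, demo = demo, seed = seed,
              out_dir = out_dir)
  .validate_config(cfg)
  structure(cfg, class = "run_config")
}

.CONFIG_KEYS <- c("whisker_params", "grid_params", "solver", "uniqueness",
                  "sensitivity", "demo", "seed", "out_dir")

.validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  .assert(length(unknown) == 0,
          paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  .assert(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed must be a number")
  invisible(TRUE)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param cfg a [run_config()].
#' @param path YAML path.
#' @return `path` invisibly (write); a `run_config` (read).
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Run the full pipeline
#'
#' Stages: build the whisker, sweep the reachable-space grid into a mapping
#' table, run the uniqueness census, optionally the sensitivity analysis and
#' the whisk-against-a-peg demo with reconstruction. Every run writes its
#' resolved configuration and a stage log next to the outputs; all
#' randomness derives from the config seed.
#'
#' @param cfg a [run_config()].
#' @param progress forwarded to the sweep.
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(cfg, progress = 0) {
  .validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out_dir, "run.log")
  logcon <- file(logf, "w")
  on.exit(close(logcon))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    v <- expr
    writeLines(sprintf("%s: %.1f s", name,
                       as.numeric(Sys.time() - t0, units = "secs")), logcon)
    v
  }
  write_config(cfg, file.path(cfg$out_dir, "resolved_config.yaml"))
  whisker <- stage("whisker", {
    if (!is.null(cfg$whisker_params$file))
      load_whisker_points(cfg$whisker_params$file)
    else do.call(build_gamma_like_whisker, cfg$whisker_params)
  })
  write_whisker_points(whisker, file.path(cfg$out_dir, "whisker.csv"))
  grid <- do.call(build_grid, cfg$grid_params)
  opts <- do.call(solver_options, cfg$solver)
  table <- stage("sweep", build_mapping(whisker, grid, opts,
                                        progress = progress))
  writeLines(sprintf("sweep records: %d converged, %d discarded, %d excluded",
                     table$n_converged, table$n_discarded, table$n_excluded),
             logcon)
  write_mapping_table(table, file.path(cfg$out_dir, "mapping_table.csv"))
  if (isTRUE(cfg$uniqueness$run %||% TRUE)) {
    thr <- do.call(uniqueness_thresholds,
                   cfg$uniqueness$thresholds %||% list())
    census <- stage("uniqueness", uniqueness_census(
      table, condition = cfg$uniqueness$condition %||% "All",
      thresholds = thr, seeds = cfg$uniqueness$seeds %||% (cfg$seed + 1:3),
      min_records = cfg$uniqueness$min_records %||% 1000))
    write_uniqueness_report(census, file.path(cfg$out_dir, "uniqueness.json"))
    writeLines(paste("unique triplets:",
                     paste(census$unique, collapse = " ")), logcon)
  }
  traj <- NULL
  if (isTRUE(cfg$demo$run)) {
    demo_args <- cfg$demo[setdiff(names(cfg$demo), "run")]
    demo_args$whisker <- whisker
    demo_args$seed <- demo_args$seed %||% (cfg$seed + 5)
    traj <- stage("demo", do.call(synth_whisk_trial, demo_args))
    traj <- lowpass_basepose(traj, whisker)
    sig <- stage("demo_signals", trial_to_signals(traj, whisker, opts))
    write_trajectory(traj, file.path(cfg$out_dir, "trajectory.csv"))
    rec <- stage("reconstruction",
                 reconstruct_peg(sig, traj, whisker, table))
    write.csv(rec$points, file.path(cfg$out_dir, "reconstruction.csv"),
              row.names = FALSE)
    writeLines(sprintf(
      "reconstruction: %d frames, median radial %.3f mm, angular %.3f mm",
      rec$n_frames, rec$median_radial_err_mm, rec$median_angular_err_mm),
      logcon)
    if (isTRUE(cfg$sensitivity$run)) {
      env <- signal_envelope(sig[sig$in_contact & sig$solved, ])
      steps <- step_from_range(env)
      rr <- retained_records(table)
      inenv <- rr$MD_rad >= env$MD_rad[1] & rr$MD_rad <= env$MD_rad[2] &
        rr$MB >= env$MB[1] & rr$MB <= env$MB[2] &
        rr$Fx >= env$Fx[1] & rr$Fx <= env$Fx[2]
      probes <- rr[inenv & is.finite(rr$MD_rad), c("MD_rad", "MB", "Fx")]
      jf <- stage("sensitivity", jacobian_at(probes, table, steps,
                                             k = cfg$sensitivity$k %||% 24))
      bs <- trim_and_bin(jf, min_valid = min(100, nrow(probes)))
      write_binned_sensitivity(bs, file.path(cfg$out_dir, "sensitivity.json"))
    }
  }
  invisible(cfg$out_dir)
}
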