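#' Read a build configuration from JSON
#'
#' Keys are named exactly as the [build_config()] fields (`L`, `E`, `R`,
#' `wobble_layout` as an array of `{x, y}` records, `wobble_on_factor`,
#' `wobble_off_factor`, `cut_excess`, `include_cut_x`, `include_cut_y`,
#' plus an optional `rates` record with [rate_params()] fields).
#'
#' @param path JSON file path.
#' @return A `ccr_config`.
#' @export
read_build_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rates <- if (!is.null(j$rates)) do.call(rate_params, as.list(j$rates)) else rate_params()
  args <- j[setdiff(names(j), "rates")]
  known <- names(formals(build_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown))
    stop("Unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(build_config, c(args, list(rates = rates)))
}

#' Write a build configuration to JSON
#'
#' @param config A `ccr_config`.
#' @param path Output path.
#' @export
write_build_config <- function(config, path) {
  stopifnot(inherits(config, "ccr_config"))
  x <- unclass(config)
  x$rates <- unclass(x$rates)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Serialize a model to JSON for inspection
#'
#' Writes the slat table, site table, compatibility map and initial bonds,
#' together with the generating configuration.
#'
#' @param spec A `ccr_model`.
#' @param path Output path.
#' @export
write_model_json <- function(spec, path) {
  stopifnot(inherits(spec, "ccr_model"))
  x <- list(config = {
    cfg <- unclass(spec$config); cfg$rates <- unclass(cfg$rates); cfg
  },
  slats = spec$slats, sites = spec$sites, compatibility = spec$compat,
  initial_bonds = spec$initial_bonds, n_half = spec$n_half)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Write a trajectory's samples as CSV
#'
#' Columns: `time`, `tracked_complex_size`, `n_complexes`,
#' `largest_complex_size`, `bridging`. The optional event log is written to
#' `<path>.events.json` when present and `events = TRUE`.
#'
#' @param trajectory A `ccr_trajectory`.
#' @param path CSV output path.
#' @param events Also write the event log JSON if available.
#' @export
write_trajectory_csv <- function(trajectory, path, events = FALSE) {
  stopifnot(inherits(trajectory, "ccr_trajectory"))
  utils::write.csv(trajectory$samples, path, row.names = FALSE)
  if (events && !is.null(trajectory$events))
    jsonlite::write_json(trajectory$events, paste0(path, ".events.json"), digits = NA)
  invisible(path)
}

#' Write an ensemble manifest
#'
#' Records seeds, per-replicate termination reasons and the condition
#' descriptor for a list of trajectories.
#'
#' @param trajectories List of `ccr_trajectory`.
#' @param path JSON output path.
#' @export
write_ensemble_manifest <- function(trajectories, path) {
  m <- list(
    n = length(trajectories),
    condition = trajectories[[1]]$condition,
    mode = trajectories[[1]]$mode,
    seeds = vapply(trajectories, function(x) x$seed, 0),
    termination = vapply(trajectories, function(x) x$termination, ""),
    t_end = vapply(trajectories, function(x) x$t_end, 0))
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a population trajectory as CSV
#'
#' Columns `time`, `count`, `mass`; the final length histogram goes to
#' `<path>.lengths.csv`.
#'
#' @param traj A `ccr_population`.
#' @param path CSV output path.
#' @export
write_population_csv <- function(traj, path) {
  stopifnot(inherits(traj, "ccr_population"))
  utils::write.csv(data.frame(time = traj$times, count = traj$counts, mass = traj$mass),
                   path, row.names = FALSE)
  utils::write.csv(data.frame(length = traj$lengths[[length(traj$lengths)]]),
                   paste0(path, ".lengths.csv"), row.names = FALSE)
  invisible(path)
}

#' Command-line interface
#'
#' Subcommands: `build` (config JSON to model JSON), `run` (config to
#' trajectory CSV), `sweep` (grid JSON to summary CSV), `coarse`
#' (parameters to population CSV), `export-kappa` (config to `.ka` text).
#' Installed as the executable script `crisscut` under
#' `system.file("scripts", package = "crisscut")`.
#'
#' @param args Character vector of command-line arguments (default: the
#'   process arguments).
#' @return Exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: crisscut <build|run|sweep|coarse|export-kappa> [options]",
    "  common options: --config <json> --out <path> --seed <int> --mode <standard|prebound>",
    "  run:    --t-max <real> --audit",
    "  sweep:  --grid <json> --n <int>",
    "  coarse: --v <real> --delta <real> --lambda <real> --t-max <real>",
    sep = "\n")
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list(seed = 1L, mode = "standard", out = NULL, config = NULL,
              grid = NULL, n = 100L, t_max = 3000, v = 1, delta = 1,
              lambda = 1, audit = FALSE)
  i <- 2L
  while (i <= length(args)) {
    a <- args[i]
    take <- function() { i <<- i + 1L; args[i] }
    switch(a,
      "--config" = opt$config <- take(),
      "--out" = opt$out <- take(),
      "--seed" = opt$seed <- as.integer(take()),
      "--mode" = opt$mode <- take(),
      "--grid" = opt$grid <- take(),
      "--n" = opt$n <- as.integer(take()),
      "--t-max" = opt$t_max <- as.numeric(take()),
      "--v" = opt$v <- as.numeric(take()),
      "--delta" = opt$delta <- as.numeric(take()),
      "--lambda" = opt$lambda <- as.numeric(take()),
      "--audit" = opt$audit <- TRUE,
      stop("Unknown option: ", a, call. = FALSE))
    i <- i + 1L
  }
  if (is.null(opt$out)) stop("--out is required", call. = FALSE)
  need_config <- function() {
    if (is.null(opt$config)) stop("--config is required", call. = FALSE)
    read_build_config(opt$config)
  }
  switch(cmd,
    build = {
      spec <- build_scission_model(need_config())
      rep <- validate_model(spec)
      if (!all(rep$pass)) { print(rep); stop("model validation failed", call. = FALSE) }
      write_model_json(spec, opt$out)
      message("model written to ", opt$out)
    },
    run = {
      spec <- build_scission_model(need_config())
      tr <- run_scission(spec, mode = opt$mode, seed = opt$seed,
                         t_max = opt$t_max, audit = opt$audit)
      write_trajectory_csv(tr, opt$out)
      sc <- detect_scission(tr, spec)
      message(sprintf("termination %s at t=%.4g; scission time %s",
                      tr$termination, tr$t_end,
                      if (sc$censored) "censored" else sprintf("%.4g", sc$scission_time)))
    },
    sweep = {
      if (is.null(opt$grid)) stop("--grid is required", call. = FALSE)
      grid <- jsonlite::read_json(opt$grid, simplifyVector = TRUE)
      base_cfg <- if (!is.null(opt$config)) need_config() else build_config(L = 10)
      sm <- sweep_conditions(grid, base_config = base_cfg, mode = opt$mode,
                             n = opt$n, base_seed = opt$seed, t_max = opt$t_max)
      utils::write.csv(sm, opt$out, row.names = FALSE)
      message("sweep summary written to ", opt$out)
    },
    coarse = {
      pp <- coarse_params(v = opt$v, Delta = opt$delta, lambda = opt$lambda,
                          t_max = opt$t_max)
      tr <- simulate_population(pp, seed = opt$seed)
      write_population_csv(tr, opt$out)
      am <- amplification_metrics(tr)
      message(sprintf("%d ribbons at t_max; doubling time %s",
                      tr$counts[length(tr$counts)],
                      if (is.na(am$doubling_time)) "undefined" else sprintf("%.4g", am$doubling_time)))
    },
    "export-kappa" = {
      spec <- build_scission_model(need_config())
      km <- export_kappa(spec, mode = opt$mode)
      writeLines(render_kappa(km), opt$out, sep = "")
      message("kappa model written to ", opt$out)
    },
    { message(usage); return(invisible(1L)) })
  invisible(0L)
}
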