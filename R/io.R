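# CSV and configuration I/O, plus the config-driven run dispatcher.

OBS_TYPES <- c("od_wt_only", "od_coculture", "freq_protease_deficient",
               "freq_antibiotic_resistant")

#' Read and write observation series CSV files
#'
#' The on-disk dialect has columns `time_h`, `value`, `data_type`,
#' `replicate`. Unknown data-type tags are rejected with a diagnostic
#' listing the allowed tags. Frequencies are stored on the 0-100 percent
#' scale and densities in OD600 units.
#'
#' @param x an [observation_series()] (or compatible data frame).
#' @param path file path.
#' @return `read_observations()` returns an `observation_series`;
#'   `write_observations()` returns `path` invisibly.
#' @export
write_observations <- function(x, path) {
  need <- c("time_h", "value", "data_type", "replicate")
  if (!all(need %in% names(x))) {
    stop("observations need columns ", paste(need, collapse = ", "))
  }
  write.csv(as.data.frame(x)[, need], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(time_h = "numeric", value = "numeric",
                                data_type = "character",
                                replicate = "character"))
  bad <- setdiff(unique(df$data_type), OBS_TYPES)
  if (length(bad)) {
    stop(sprintf("%s: unknown data_type tag(s) %s; allowed: %s", path,
                 paste(bad, collapse = ", "),
                 paste(OBS_TYPES, collapse = ", ")))
  }
  observation_series(df$time_h, df$value, df$data_type, df$replicate)
}

#' Read and write trajectory CSV files
#'
#' Columns are `time_h`, the state components (`S`, `P`, `E` in mmol/l;
#' `X1`, `X2` and optionally `X3` in g dry weight/l), plus the derived
#' `od600_total` and `cheater_frequency` (percent; protease-deficient
#' phenotype for evolved variants).
#'
#' @param traj a `chemostat_trajectory`.
#' @param path file path.
#' @return `read_trajectory()` returns a data frame;
#'   `write_trajectory()` returns `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  df$od600_total <- od600_total(traj)
  df$cheater_frequency <- phenotype_frequencies(traj)$pd_percent
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read a run configuration file
#'
#' YAML file with a `command` (one of `simulate`, `simulate-evolved`,
#' `fit`, `sweep`, `heatmap`, `synth`), an optional `seed`, optional
#' `parameters`, `initial_state` and `schedule` sections (keys named as
#' the corresponding constructor arguments), and per-command options.
#'
#' @param path YAML file path.
#' @return A validated list of class `run_config` (with the source path
#'   kept for provenance hashing).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  allowed <- c("simulate", "simulate-evolved", "fit", "sweep", "heatmap",
               "synth")
  if (is.null(cfg$command) || !cfg$command %in% allowed) {
    stop("config must set command to one of: ",
         paste(allowed, collapse = ", "))
  }
  cfg$config_path <- path
  structure(cfg, class = "run_config")
}

config_params <- function(cfg) {
  do.call(model_parameters, as.list(cfg$parameters %||% list()))
}

config_schedule <- function(cfg, default_batch, default_chemo) {
  s <- cfg$schedule %||% list()
  culture_schedule(s$batch_hours %||% default_batch,
                   s$chemostat_hours %||% default_chemo,
                   s$sample_times)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute a run configuration
#'
#' Dispatches the configured command to the corresponding package
#' function and writes its artifacts (CSV) together with a
#' `manifest.json` recording the package version, seed and an MD5 hash
#' of the configuration file.
#'
#' @param config a [read_run_config()] result or a path to a YAML file.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a named list of written artifact paths.
#' @export
run_chemostat <- function(config, out_dir = ".") {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1
  set.seed(seed)
  artifacts <- list()
  out <- function(name) file.path(out_dir, name)

  if (config$command == "simulate") {
    p <- config_params(config)
    scenario <- config$scenario %||% "wt_only"
    sched <- config_schedule(config, if (scenario == "wt_only") 32 else 55,
                             192)
    init <- initial_state(scenario, p,
                          E0 = config$initial_state$E0 %||% 3.00e-6)
    traj <- simulate_chemostat(p, sched, init, scenario = scenario)
    artifacts$trajectory <- write_trajectory(traj, out("trajectory.csv"))
  } else if (config$command == "simulate-evolved") {
    p <- config_params(config)
    ep <- evolved_parameters(p, alpha = config$alpha,
                             mu_max_2 = config$mu_max_2,
                             variant = config$variant)
    sched <- config_schedule(config, 55, 192)
    traj <- simulate_evolved(ep, sched)
    artifacts$trajectory <- write_trajectory(traj, out("trajectory.csv"))
  } else if (config$command == "synth") {
    sc_args <- config$synthetic %||% list()
    sc_args$seed <- seed
    ds <- generate_dataset(do.call(synthetic_config, sc_args))
    artifacts$observations <- write_observations(ds,
                                                 out("observations.csv"))
  } else if (config$command == "fit") {
    data <- read_observations(config$data)
    fit <- fit_pipeline(
      data,
      scheme = sampling_scheme(config$scheme %||% "round2"),
      n_draws = config$draws %||% 1000, seed = seed,
      keep_fraction = config$keep_fraction %||% 0.10,
      weights = config$weights %||% c(0.4, 0.6, 0.2),
      exclude_replicates = config$exclude_replicates)
    if (!is.null(fit$results)) {
      utils::write.csv(as.data.frame(fit$results),
                       out("ranked_candidates.csv"), row.names = FALSE)
      artifacts$candidates <- out("ranked_candidates.csv")
    }
    report <- list(n_draws = fit$n_draws, n_success = fit$n_success,
                   failure_histogram = as.list(fit$failure_histogram),
                   best = if (is.null(fit$best)) NULL else
                     list(params = unclass(fit$best$params),
                          E0 = fit$best$E0,
                          objective = fit$best$objective,
                          rmses = as.list(fit$best$rmses)))
    jsonlite::write_json(report, out("fit_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    artifacts$report <- out("fit_report.json")
  } else if (config$command == "sweep") {
    p <- config_params(config)
    sw <- parameter_sweep(config$parameter, unlist(config$values), p)
    utils::write.csv(sw, out("sweep.csv"), row.names = FALSE)
    artifacts$sweep <- out("sweep.csv")
  } else if (config$command == "heatmap") {
    p <- config_params(config)
    data <- read_observations(config$data)
    hm <- pairwise_rmse_map(config$param1, config$param2,
                            unlist(config$range1), unlist(config$range2),
                            data, config$data_type,
                            resolution = config$resolution %||% 41,
                            base = p)
    utils::write.csv(hm, out("heatmap.csv"), row.names = FALSE)
    artifacts$heatmap <- out("heatmap.csv")
  }

  manifest <- list(package = "chemocoop",
                   version = as.character(utils::packageVersion("chemocoop")),
                   command = config$command, seed = seed,
                   config_md5 = if (!is.null(config$config_path))
                     unname(tools::md5sum(config$config_path))
                   else NA)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  artifacts$manifest <- file.path(out_dir, "manifest.json")
  invisible(artifacts)
}
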