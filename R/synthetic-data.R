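# Generation of pseudo-experimental datasets with the structure and noise
# of chemostat measurements: daily OD600 readings and colony-patching
# phenotype frequencies.

#' Configuration for synthetic dataset generation
#'
#' Describes the "true" system and the measurement process emulated by
#' [generate_dataset()]: WT-only and coculture protocols sampled at the
#' batch start, the batch end (t = 0) and roughly daily thereafter;
#' multiplicative mean-one lognormal OD noise; and phenotype frequencies
#' estimated by patching a limited number of colonies per sample
#' (binomial sampling noise). Individual coculture replicates can carry a
#' mutation-event injection, replacing their truth with an evolved-mutant
#' variant simulation.
#'
#' @param params true [model_parameters()].
#' @param E0 true initial enzyme concentration (mmol/l).
#' @param batch_hours_wt,batch_hours_co batch durations (h).
#' @param chemostat_hours chemostat duration (h).
#' @param cadence sampling interval during chemostat mode (h).
#' @param od_cv coefficient of variation of the multiplicative OD noise.
#' @param n_colonies colonies patched per sample (`Inf` for exact
#'   frequencies).
#' @param n_replicates_wt,n_replicates_co replicate counts.
#' @param od_detection_limit OD values below this report as 0.
#' @param seed integer seed; the dataset is a deterministic function of
#'   the configuration and seed.
#' @param injections named list (names = coculture replicate ids as
#'   character) of lists with `variant`, `alpha`, `mu_max_2`.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(params = model_parameters(), E0 = 3.00e-6,
                             batch_hours_wt = 32, batch_hours_co = 55,
                             chemostat_hours = 192, cadence = 24,
                             od_cv = 0.05, n_colonies = 100,
                             n_replicates_wt = 2, n_replicates_co = 4,
                             od_detection_limit = 0.001,
                             seed = 1, injections = list()) {
  stopifnot(od_cv >= 0, n_colonies >= 1, cadence > 0,
            n_replicates_wt >= 0, n_replicates_co >= 0)
  bad <- setdiff(names(injections),
                 as.character(seq_len(n_replicates_co)))
  if (length(bad)) stop("injection for unknown replicate: ",
                        paste(bad, collapse = ", "))
  structure(list(params = params, E0 = E0,
                 batch_hours_wt = batch_hours_wt,
                 batch_hours_co = batch_hours_co,
                 chemostat_hours = chemostat_hours, cadence = cadence,
                 od_cv = od_cv, n_colonies = n_colonies,
                 n_replicates_wt = n_replicates_wt,
                 n_replicates_co = n_replicates_co,
                 od_detection_limit = od_detection_limit,
                 seed = seed, injections = injections),
            class = "synthetic_config")
}

# sample grid: batch start, flow start, then every `cadence` h
synth_times <- function(batch_hours, chemostat_hours, cadence) {
  unique(c(-batch_hours, 0, seq(0, chemostat_hours, by = cadence),
           chemostat_hours))
}

noisy_od <- function(od_true, cv, detection_limit) {
  od <- if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    od_true * rlnorm(length(od_true), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else od_true
  od[od < detection_limit] <- 0
  od
}

noisy_freq <- function(freq_true, n_colonies) {
  out <- freq_true
  ok <- !is.na(freq_true)
  if (is.finite(n_colonies)) {
    out[ok] <- 100 * rbinom(sum(ok), n_colonies, freq_true[ok] / 100) /
      n_colonies
  }
  out
}

#' Generate a synthetic chemostat dataset
#'
#' Simulates the true dynamics for every replicate (base model, or an
#' evolved-mutant variant where an injection is configured), samples them
#' on the configured grid, and applies the measurement model: mean-one
#' lognormal multiplicative noise and a detection limit on OD600, and
#' binomial colony-patching noise on phenotype frequencies (observed
#' frequencies are exact multiples of `100 / n_colonies`).
#'
#' @param config a [synthetic_config()].
#' @return A data frame of class `synthetic_dataset` (columns `time_h`,
#'   `value`, `data_type`, `replicate`) with attributes `truth` (the
#'   generating parameters, `E0` and injections) and `config`.
#' @examples
#' d <- generate_dataset(synthetic_config(n_replicates_co = 1, seed = 7))
#' table(d$data_type)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  p <- config$params
  rows <- list()

  t_wt <- synth_times(config$batch_hours_wt, config$chemostat_hours,
                      config$cadence)
  if (config$n_replicates_wt > 0) {
    sched <- culture_schedule(config$batch_hours_wt,
                              config$chemostat_hours, t_wt)
    traj <- simulate_chemostat(p, sched,
                               initial_state("wt_only", p, config$E0))
    od_true <- od600_total(traj)
    for (r in seq_len(config$n_replicates_wt)) {
      rows[[length(rows) + 1]] <- observation_series(
        traj$time_h,
        noisy_od(od_true, config$od_cv, config$od_detection_limit),
        "od_wt_only", paste0("WT", r))
    }
  }

  t_co <- synth_times(config$batch_hours_co, config$chemostat_hours,
                      config$cadence)
  sched_co <- culture_schedule(config$batch_hours_co,
                               config$chemostat_hours, t_co)
  for (r in seq_len(config$n_replicates_co)) {
    inj <- config$injections[[as.character(r)]]
    if (is.null(inj)) {
      traj <- simulate_chemostat(p, sched_co,
                                 initial_state("coculture", p, config$E0),
                                 scenario = "coculture")
    } else {
      ep <- evolved_parameters(p, alpha = inj$alpha,
                               mu_max_2 = inj$mu_max_2,
                               variant = inj$variant)
      traj <- simulate_evolved(ep, sched_co)
    }
    ph <- phenotype_frequencies(traj)
    rep_id <- paste0("R", r)
    rows[[length(rows) + 1]] <- observation_series(
      traj$time_h,
      noisy_od(od600_total(traj), config$od_cv,
               config$od_detection_limit),
      "od_coculture", rep_id)
    rows[[length(rows) + 1]] <- observation_series(
      traj$time_h, noisy_freq(ph$pd_percent, config$n_colonies),
      "freq_protease_deficient", rep_id)
    rows[[length(rows) + 1]] <- observation_series(
      traj$time_h, noisy_freq(ph$ar_percent, config$n_colonies),
      "freq_antibiotic_resistant", rep_id)
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            class = c("synthetic_dataset", "observation_series",
                      "data.frame"),
            truth = list(params = p, E0 = config$E0,
                         injections = config$injections),
            config = config)
}

#' Fixed benchmark fixture set
#'
#' Three deterministic datasets used throughout the test suite:
#' * `clean` - noiseless best-fit data (no OD noise, exact frequencies),
#'   suitable for parameter-recovery experiments;
#' * `noisy` - a four-replicate coculture dataset at default noise, with
#'   one replicate carrying a faster-growing cheater evolved from the WT
#'   and one a faster-growing cooperator;
#' * `toy` - a tiny three-time-point coculture set for exact unit tests.
#'
#' @param seed integer seed.
#' @return Named list of `synthetic_dataset`s.
#' @export
make_benchmark_suite <- function(seed = 20240410) {
  list(
    clean = generate_dataset(synthetic_config(
      od_cv = 0, n_colonies = Inf, seed = seed)),
    noisy = generate_dataset(synthetic_config(
      seed = seed + 1,
      injections = list(
        "4" = list(variant = "cheater_from_WT", alpha = 7e-7,
                   mu_max_2 = 4.0),
        "2" = list(variant = "cooperator_from_WT", alpha = 3e-5,
                   mu_max_2 = 4.0)))),
    toy = generate_dataset(synthetic_config(
      od_cv = 0, n_colonies = Inf, n_replicates_wt = 1,
      n_replicates_co = 1, chemostat_hours = 24, cadence = 24,
      seed = seed + 2)))
}
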