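# Ensemble parameter sampling, success filtering, weighted normalized RMSE
# scoring, candidate selection, and greedy refinement.

#' Success criteria for a sampled parameter set
#'
#' A simulation captures the general dynamics of the chemostat data when
#' (i) the WT-only culture keeps a positive cooperator density at the
#' final time point (no washout), (ii) the coculture batch phase does not
#' overshoot a plausible maximum density, and (iii) the cheater frequency
#' reaches at least a minimum level by the final chemostat time point.
#'
#' @param min_final_wt_biomass threshold for (i), g dry weight/l.
#' @param max_coculture_batch_od threshold for (ii), OD600.
#' @param min_cheater_freq threshold for (iii), percent.
#' @return A list of class `success_criteria`.
#' @export
success_criteria <- function(min_final_wt_biomass = 0.01,
                             max_coculture_batch_od = 0.58,
                             min_cheater_freq = 30) {
  stopifnot(min_final_wt_biomass > 0, max_coculture_batch_od > 0,
            min_cheater_freq > 0)
  structure(list(min_final_wt_biomass = min_final_wt_biomass,
                 max_coculture_batch_od = max_coculture_batch_od,
                 min_cheater_freq = min_cheater_freq),
            class = "success_criteria")
}

#' Sampling scheme for the ensemble calibration
#'
#' Ranged parameters (and the initial enzyme concentration `E0`) are drawn
#' uniformly from their estimated ranges; point-estimated parameters
#' (`mu_max`, `K_S`, `gamma`) are either drawn from a normal distribution
#' with a standard deviation of 10 percent of the mean (`"round1"`) or
#' held at their single estimates (`"round2"`). The dilution rate `D` and
#' Hill coefficient `n` are always fixed. Round 2 additionally raises the
#' lower bounds of `k_cat` to 150 and of `eta` to `4e-4`, the smallest
#' values found to still produce successful dynamics in a first broad
#' screen.
#'
#' @param round `"round2"` (default) or `"round1"`.
#' @param ranges optional named list overriding individual sampling ranges
#'   (length-2 `c(lower, upper)` vectors).
#' @return A list of class `sampling_scheme`.
#' @export
sampling_scheme <- function(round = c("round2", "round1"), ranges = list()) {
  round <- match.arg(round)
  rg <- parameter_ranges()
  if (round == "round2") {
    rg$k_cat[1] <- 150
    rg$eta[1] <- 4e-4
  }
  for (nm in names(ranges)) {
    if (!nm %in% names(rg)) stop("unknown ranged parameter: ", nm)
    stopifnot(length(ranges[[nm]]) == 2, ranges[[nm]][1] < ranges[[nm]][2])
    rg[[nm]] <- ranges[[nm]]
  }
  structure(list(round = round, ranged = rg,
                 point = c(mu_max = 1.38, K_S = 0.840, gamma = 0.0423),
                 point_sd_frac = if (round == "round1") 0.10 else 0,
                 fixed = c(D = 0.121, n = 2)),
            class = "sampling_scheme")
}

#' Draw random parameter sets from a sampling scheme
#'
#' @param scheme a [sampling_scheme()].
#' @param n number of draws.
#' @param seed optional integer seed for reproducibility.
#' @return A data frame with one row per draw and one column per
#'   parameter (including `E0`, `D` and `n`).
#' @examples
#' sample_parameters(sampling_scheme(), 3, seed = 1)
#' @export
sample_parameters <- function(scheme, n, seed = NULL) {
  stopifnot(inherits(scheme, "sampling_scheme"), n >= 0)
  if (!is.null(seed)) set.seed(seed)
  draws <- as.data.frame(lapply(scheme$ranged, function(r) {
    x <- runif(n, r[1], r[2])
    # open lower bounds (E0, round-1 eta): redraw exact-zero values
    while (r[1] == 0 && any(x == 0)) x[x == 0] <- runif(sum(x == 0), 0, r[2])
    x
  }))
  for (nm in names(scheme$point)) {
    m <- scheme$point[[nm]]
    if (scheme$point_sd_frac > 0) {
      x <- rnorm(n, m, scheme$point_sd_frac * m)
      while (any(x <= 0)) {
        x[x <= 0] <- rnorm(sum(x <= 0), m, scheme$point_sd_frac * m)
      }
      draws[[nm]] <- x
    } else {
      draws[[nm]] <- rep(m, n)
    }
  }
  for (nm in names(scheme$fixed)) draws[[nm]] <- rep(scheme$fixed[[nm]], n)
  if (n == 0) draws <- draws[0, , drop = FALSE]
  draws
}

# A draw row -> (model_parameters, E0)
draw_setup <- function(draw) {
  params <- model_parameters(S0 = draw$S0, D = draw$D,
                             mu_max = draw$mu_max, k_cat = draw$k_cat,
                             K_S = draw$K_S, K_M = draw$K_M,
                             eta = draw$eta, gamma = draw$gamma,
                             sigma = draw$sigma, q = draw$q,
                             QS_min = draw$QS_min, n = draw$n)
  list(params = params, E0 = draw$E0)
}

# Default protocols used throughout the calibration pipeline.
default_schedules <- function(sample_times_chemo = seq(0, 192, by = 4)) {
  list(wt = culture_schedule(32, 192,
         sample_times = unique(c(seq(-32, 0, by = 1), sample_times_chemo))),
       co = culture_schedule(55, 192,
         sample_times = unique(c(seq(-55, 0, by = 1), sample_times_chemo))))
}

# Simulate both scenarios for one parameter set; NULL on solver failure.
simulate_scenarios <- function(params, E0, schedules = default_schedules()) {
  out <- try({
    wt <- simulate_chemostat(params, schedules$wt,
                             initial_state("wt_only", params, E0),
                             scenario = "wt_only")
    co <- simulate_chemostat(params, schedules$co,
                             initial_state("coculture", params, E0),
                             scenario = "coculture")
    list(wt = wt, co = co)
  }, silent = TRUE)
  if (inherits(out, "try-error")) NULL else out
}

#' Evaluate the success criteria for one parameter set
#'
#' Simulates the WT-only and coculture protocols and checks the three
#' [success_criteria()]. Solver failures are reported as a failure with
#' reason `"numerical"`.
#'
#' @param params a [model_parameters()] object.
#' @param E0 initial enzyme concentration (mmol/l).
#' @param criteria a [success_criteria()].
#' @param schedules list with `wt` and `co` [culture_schedule()]s.
#' @param sims optional pre-computed result of an internal scenario
#'   simulation, to avoid re-integration.
#' @return A list with `pass`, per-criterion `flags`, the measured
#'   `metrics`, the failure `reasons`, and the simulations (`sims`).
#' @export
evaluate_success <- function(params, E0 = 3.00e-6,
                             criteria = success_criteria(),
                             schedules = default_schedules(),
                             sims = NULL) {
  if (is.null(sims)) sims <- simulate_scenarios(params, E0, schedules)
  if (is.null(sims)) {
    return(list(pass = FALSE,
                flags = c(wt_persists = NA, batch_od = NA, cheater_freq = NA),
                metrics = c(final_wt_biomass = NA, max_batch_od = NA,
                            final_cheater_freq = NA),
                reasons = "numerical", sims = NULL))
  }
  final_wt <- sims$wt$X1[nrow(sims$wt)]
  batch <- sims$co[sims$co$time_h <= 0, ]
  max_batch_od <- max(biomass_to_od(batch$X1 + batch$X2))
  freq <- cheater_frequency(sims$co)$value
  final_freq <- freq[length(freq)]
  flags <- c(
    wt_persists = final_wt > criteria$min_final_wt_biomass,
    batch_od = max_batch_od < criteria$max_coculture_batch_od,
    cheater_freq = !is.na(final_freq) &&
      final_freq >= criteria$min_cheater_freq)
  list(pass = all(flags),
       flags = flags,
       metrics = c(final_wt_biomass = final_wt,
                   max_batch_od = max_batch_od,
                   final_cheater_freq = final_freq),
       reasons = names(flags)[!flags],
       sims = sims)
}

#' Root mean square error between a simulation and observations
#'
#' The simulated series is interpolated linearly onto the observed sample
#' times; the RMSE is computed per replicate and averaged (unweighted)
#' across replicates of the data type.
#'
#' @param simulated an [observation_series()] from a simulation.
#' @param observed an [observation_series()] with one or more replicates.
#' @return Mean per-replicate RMSE.
#' @examples
#' s <- observation_series(c(0, 24), c(0.3, 0.3), "od_coculture", "sim")
#' o <- observation_series(c(0, 24), c(0.2, 0.4), "od_coculture", "1")
#' rmse(s, o)  # 0.1
#' @export
rmse <- function(simulated, observed) {
  obs <- observed[!is.na(observed$value), , drop = FALSE]
  if (!nrow(obs)) stop("no usable observations")
  lo <- min(simulated$time_h); hi <- max(simulated$time_h)
  per_rep <- vapply(split(obs, obs$replicate), function(rep_df) {
    tt <- rep_df$time_h
    if (!any(tt >= lo - 1e-9 & tt <= hi + 1e-9)) {
      stop("no overlap between simulated and observed times")
    }
    keep <- tt >= lo - 1e-9 & tt <= hi + 1e-9
    pred <- approx(simulated$time_h, simulated$value, xout = tt[keep],
                   ties = "ordered")$y
    sqrt(mean((pred - rep_df$value[keep])^2))
  }, numeric(1))
  mean(per_rep)
}

# RMSEs of one simulated parameter set against the three fitted data types.
fit_rmses <- function(sims, datasets) {
  types <- c(wt = "od_wt_only", co = "od_coculture",
             freq = "freq_protease_deficient")
  vapply(types, function(ty) {
    obs <- datasets[datasets$data_type == ty, , drop = FALSE]
    if (!nrow(obs)) return(NA_real_)
    rmse(simulated_series(sims, ty), obs)
  }, numeric(1))
}

#' Combine per-data-type RMSEs into a ranked ensemble score
#'
#' Each RMSE column is rescaled to `[0, 1]` by max-min normalization
#' across the ensemble, then combined as a weighted sum (defaults 0.4 for
#' WT-only density, 0.6 for coculture density, 0.2 for cheater
#' frequency). A degenerate column (max = min) normalizes to 0.
#'
#' @param results data frame with columns `rmse_wt`, `rmse_co`,
#'   `rmse_freq`.
#' @param weights length-3 weights for the three data types.
#' @return `results` with added `norm_*` and `combined` columns, sorted
#'   by ascending combined score.
#' @export
combine_scores <- function(results, weights = c(0.4, 0.6, 0.2)) {
  stopifnot(length(weights) == 3)
  norm01 <- function(x) {
    r <- range(x)
    if (diff(r) == 0) rep(0, length(x)) else (x - r[1]) / diff(r)
  }
  results$norm_wt <- norm01(results$rmse_wt)
  results$norm_co <- norm01(results$rmse_co)
  results$norm_freq <- norm01(results$rmse_freq)
  results$combined <- weights[1] * results$norm_wt +
    weights[2] * results$norm_co + weights[3] * results$norm_freq
  results[order(results$combined), , drop = FALSE]
}

#' Select candidate fits from a ranked ensemble
#'
#' Keeps the fraction of the ensemble with the lowest combined score,
#' then drops candidates whose simulated end-of-batch (t = 0) coculture
#' density falls outside the observed range at t = 0 or whose t = 0
#' cheater frequency is below the threshold.
#'
#' @param ranked output of [combine_scores()]; must carry columns
#'   `od_batch_end` (simulated coculture OD at t = 0) and
#'   `freq_batch_end` (simulated cheater frequency at t = 0, percent).
#' @param keep_fraction fraction of the ensemble kept before filtering.
#' @param od_bounds length-2 observed coculture OD range at t = 0.
#' @param min_freq end-of-batch cheater-frequency threshold (percent).
#' @return The filtered data frame (possibly empty).
#' @export
select_candidates <- function(ranked, keep_fraction = 0.10,
                              od_bounds, min_freq = 30) {
  stopifnot(length(od_bounds) == 2)
  n_keep <- ceiling(keep_fraction * nrow(ranked))
  top <- ranked[seq_len(min(n_keep, nrow(ranked))), , drop = FALSE]
  keep <- top$od_batch_end >= od_bounds[1] &
    top$od_batch_end <= od_bounds[2] &
    !is.na(top$freq_batch_end) & top$freq_batch_end >= min_freq
  top[keep, , drop = FALSE]
}

# Raw weighted objective used by the greedy refinement.
raw_objective <- function(params, E0, datasets, schedules,
                          weights = c(0.4, 0.6, 0.2)) {
  sims <- simulate_scenarios(params, E0, schedules)
  if (is.null(sims)) return(Inf)
  r <- fit_rmses(sims, datasets)
  if (any(is.na(r))) return(Inf)
  sum(weights * r)
}

#' Greedy local refinement of a parameter set
#'
#' Starting from a candidate fit, repeatedly tries small multiplicative
#' perturbations (default +-1 and +-5 percent) of single parameters and
#' of parameter pairs, accepting the best move that lowers the raw
#' weighted RMSE objective, until no move improves it or the step budget
#' is exhausted. This is a deterministic counterpart of adjusting
#' individual or pairs of parameters by hand until the error stops
#' decreasing.
#'
#' @param params starting [model_parameters()].
#' @param E0 starting initial enzyme concentration.
#' @param datasets observation data frame with the three fitted data
#'   types.
#' @param which names of free parameters (from the draw columns,
#'   including `"E0"`).
#' @param factors multiplicative single-parameter step factors.
#' @param pair_factors factors tried on both members of a pair.
#' @param max_iter maximum accepted moves.
#' @param weights objective weights (WT-only, coculture, frequency).
#' @param schedules simulation protocols.
#' @return A list with refined `params`, `E0`, final `objective`,
#'   `rmses`, and the number of accepted moves `steps`.
#' @export
refine <- function(params, E0, datasets,
                   which = c("S0", "E0", "k_cat", "K_M", "eta", "sigma",
                             "q", "QS_min"),
                   factors = c(0.99, 1.01, 0.95, 1.05),
                   pair_factors = c(0.95, 1.05),
                   max_iter = 50, weights = c(0.4, 0.6, 0.2),
                   schedules = default_schedules()) {
  get_val <- function(nm) if (nm == "E0") E0 else params[[nm]]
  set_val <- function(nm, v, pp, ee) {
    if (nm == "E0") ee <- v else pp[[nm]] <- v
    list(pp = pp, ee = ee)
  }
  objective <- raw_objective(params, E0, datasets, schedules, weights)
  steps <- 0
  pairs <- if (length(which) > 1) utils::combn(which, 2, simplify = FALSE)
           else list()
  repeat {
    best <- list(obj = objective)
    for (nm in which) {
      for (f in factors) {
        s <- set_val(nm, get_val(nm) * f, params, E0)
        o <- raw_objective(s$pp, s$ee, datasets, schedules, weights)
        if (o < best$obj) best <- list(obj = o, pp = s$pp, ee = s$ee)
      }
    }
    for (pr in pairs) {
      for (f1 in pair_factors) {
        for (f2 in pair_factors) {
          s <- set_val(pr[1], get_val(pr[1]) * f1, params, E0)
          s <- set_val(pr[2],
                       if (pr[2] == "E0") s$ee * f2 else s$pp[[pr[2]]] * f2,
                       s$pp, s$ee)
          o <- raw_objective(s$pp, s$ee, datasets, schedules, weights)
          if (o < best$obj) best <- list(obj = o, pp = s$pp, ee = s$ee)
        }
      }
    }
    if (best$obj >= objective - 1e-12 || is.null(best$pp)) break
    params <- best$pp; E0 <- best$ee; objective <- best$obj
    steps <- steps + 1
    if (steps >= max_iter) break
  }
  sims <- simulate_scenarios(params, E0, schedules)
  list(params = params, E0 = E0, objective = objective,
       rmses = if (is.null(sims)) c(wt = NA, co = NA, freq = NA)
               else fit_rmses(sims, datasets),
       steps = steps)
}

#' Success-filter yield of a sampling scheme
#'
#' Draws random parameter sets and counts how many pass all three
#' [success_criteria()] when simulated through both culture protocols.
#' This is the screening stage of the calibration, run on its own: large
#' ensembles are screened this way before any data fitting, and the
#' passing fraction characterizes how much of the estimated parameter
#' space is compatible with the qualitative chemostat dynamics.
#'
#' @param scheme a [sampling_scheme()].
#' @param n_draws number of draws.
#' @param seed integer seed.
#' @param criteria a [success_criteria()].
#' @param schedules simulation protocols.
#' @return A list with `n_draws`, `n_pass`, `fraction` and the
#'   per-criterion `failure_histogram`.
#' @export
success_yield <- function(scheme = sampling_scheme(), n_draws,
                          seed = 1, criteria = success_criteria(),
                          schedules = default_schedules()) {
  draws <- sample_parameters(scheme, n_draws, seed = seed)
  n_pass <- 0L
  fail_hist <- c(wt_persists = 0, batch_od = 0, cheater_freq = 0,
                 numerical = 0)
  for (i in seq_len(n_draws)) {
    setup <- draw_setup(draws[i, ])
    ev <- evaluate_success(setup$params, setup$E0, criteria, schedules)
    if (ev$pass) {
      n_pass <- n_pass + 1L
    } else {
      fail_hist[ev$reasons] <- fail_hist[ev$reasons] + 1
    }
  }
  list(n_draws = n_draws, n_pass = n_pass, fraction = n_pass / n_draws,
       failure_histogram = fail_hist)
}

#' Ensemble calibration pipeline
#'
#' Draws random parameter sets, simulates both culture protocols for
#' each, applies the [success_criteria()] filter, scores successful draws
#' by weighted max-min-normalized RMSE against the three data types,
#' keeps the lowest-scoring fraction subject to the end-of-batch filter,
#' and greedily refines the best candidate. The whole run is reproducible
#' given `seed`.
#'
#' @param datasets observation data frame (columns `time_h`, `value`,
#'   `data_type`, `replicate`) containing `od_wt_only`, `od_coculture`
#'   and `freq_protease_deficient` series.
#' @param scheme a [sampling_scheme()].
#' @param criteria a [success_criteria()].
#' @param n_draws ensemble size.
#' @param seed integer seed.
#' @param keep_fraction fraction kept by [select_candidates()].
#' @param weights RMSE weights (WT-only, coculture, frequency).
#' @param exclude_replicates replicate ids dropped from the frequency
#'   data before fitting (for discordant replicates).
#' @param refine_control list of arguments forwarded to [refine()].
#' @param schedules simulation protocols.
#' @return A list of class `chemostat_fit`: counts, per-criterion failure
#'   histogram, the scored ensemble (`results`), the candidate list, and
#'   the refined `best` fit (or `NULL` when nothing succeeded).
#' @export
fit_pipeline <- function(datasets, scheme = sampling_scheme(),
                         criteria = success_criteria(),
                         n_draws = 1000, seed = 1,
                         keep_fraction = 0.10,
                         weights = c(0.4, 0.6, 0.2),
                         exclude_replicates = NULL,
                         refine_control = list(),
                         schedules = default_schedules()) {
  if (!is.null(exclude_replicates)) {
    drop <- datasets$data_type %in%
      c("freq_protease_deficient", "freq_antibiotic_resistant") &
      datasets$replicate %in% as.character(exclude_replicates)
    datasets <- datasets[!drop, , drop = FALSE]
  }
  for (ty in c("od_wt_only", "od_coculture", "freq_protease_deficient")) {
    if (!any(datasets$data_type == ty)) {
      stop("datasets must contain data_type ", ty)
    }
  }
  draws <- sample_parameters(scheme, n_draws, seed = seed)
  rows <- vector("list", n_draws)
  fail_hist <- c(wt_persists = 0, batch_od = 0, cheater_freq = 0,
                 numerical = 0)
  for (i in seq_len(n_draws)) {
    setup <- draw_setup(draws[i, ])
    ev <- evaluate_success(setup$params, setup$E0, criteria, schedules)
    if (!ev$pass) {
      fail_hist[ev$reasons] <- fail_hist[ev$reasons] + 1
      next
    }
    r <- fit_rmses(ev$sims, datasets)
    co0 <- ev$sims$co[ev$sims$co$time_h == 0, ]
    freq0 <- 100 * co0$X2 / (co0$X1 + co0$X2)
    rows[[i]] <- cbind(draws[i, ], draw = i,
                       rmse_wt = r[["wt"]], rmse_co = r[["co"]],
                       rmse_freq = r[["freq"]],
                       od_batch_end = biomass_to_od(co0$X1 + co0$X2),
                       freq_batch_end = freq0)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(structure(list(n_draws = n_draws, n_success = 0,
                          failure_histogram = fail_hist, results = NULL,
                          candidates = NULL, best = NULL, seed = seed),
                     class = "chemostat_fit"))
  }
  results <- combine_scores(do.call(rbind, rows), weights)
  obs_co <- datasets[datasets$data_type == "od_coculture" &
                       !is.na(datasets$value), ]
  at0 <- obs_co$value[abs(obs_co$time_h) ==
                        min(abs(obs_co$time_h))]
  od_bounds <- range(at0)
  candidates <- select_candidates(results, keep_fraction, od_bounds,
                                  criteria$min_cheater_freq)
  pool <- if (nrow(candidates)) candidates else results
  best_row <- pool[1, ]
  setup <- draw_setup(best_row)
  best <- do.call(refine, c(list(params = setup$params, E0 = setup$E0,
                                 datasets = datasets,
                                 weights = weights,
                                 schedules = schedules),
                            refine_control))
  structure(list(n_draws = n_draws, n_success = length(rows),
                 failure_histogram = fail_hist, results = results,
                 candidates = candidates, best = best, seed = seed),
            class = "chemostat_fit")
}

#' @export
print.chemostat_fit <- function(x, ...) {
  cat(sprintf("Chemostat calibration: %d/%d draws passed the success filter\n",
              x$n_success, x$n_draws))
  cat("Failure histogram:\n")
  print(x$failure_histogram)
  if (!is.null(x$best)) {
    cat(sprintf("Refined best fit (objective %.5g, %d accepted moves):\n",
                x$best$objective, x$best$steps))
    print(unlist(x$best$params))
    cat(sprintf("E0 = %g\n", x$best$E0))
  }
  invisible(x)
}
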