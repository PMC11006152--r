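# Single-parameter sweeps and pairwise RMSE maps with over/undershoot
# classification.

#' Single-parameter sensitivity sweep
#'
#' Simulates the WT-only and coculture protocols for each value of one
#' parameter, holding all other parameters at the supplied base set.
#' `"E0"` may be swept as well (it is an initial condition, not a rate).
#'
#' @param parameter name of the parameter to vary.
#' @param values numeric vector of values (five values emulate the usual
#'   sensitivity panels).
#' @param base a [model_parameters()] object for the held-fixed values.
#' @param E0 initial enzyme concentration used unless `parameter = "E0"`.
#' @param schedules list with `wt` and `co` [culture_schedule()]s.
#' @param scenarios which scenarios to simulate.
#' @return A long data frame: `parameter`, `value`, `scenario`, `time_h`,
#'   `od600`, `cheater_freq` (frequency only for cocultures). Values whose
#'   integration failed are recorded in the `failed` attribute.
#' @export
parameter_sweep <- function(parameter, values, base = model_parameters(),
                            E0 = 3.00e-6,
                            schedules = default_schedules(),
                            scenarios = c("wt_only", "coculture")) {
  stopifnot(length(parameter) == 1)
  if (!parameter %in% c(names(base), "E0")) {
    stop("unknown parameter: ", parameter)
  }
  rows <- list(); failed <- numeric(0)
  for (v in values) {
    p <- base; e0 <- E0
    if (parameter == "E0") e0 <- v else p[[parameter]] <- v
    for (sc in scenarios) {
      sched <- if (sc == "wt_only") schedules$wt else schedules$co
      traj <- try(simulate_chemostat(p, sched, initial_state(sc, p, e0),
                                     scenario = sc), silent = TRUE)
      if (inherits(traj, "try-error")) {
        failed <- c(failed, v)
        next
      }
      freq <- if (sc == "coculture") cheater_frequency(traj)$value
              else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        parameter = parameter, value = v, scenario = sc,
        time_h = traj$time_h, od600 = od600_total(traj),
        cheater_freq = freq)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "failed") <- unique(failed)
  out
}

#' Pairwise RMSE map over an extended parameter plane
#'
#' Evaluates the model fit to one data type over a grid of two
#' parameters, all other parameters held at the base set. Each cell
#' stores the replicate-averaged RMSE and the sign of the pooled mean
#' residual: `+1` when the simulation on average overshoots the data,
#' `-1` when it undershoots. Cells whose integration fails are flagged
#' and excluded from the minimum.
#'
#' @param param1,param2 parameter names (may include `"E0"`).
#' @param range1,range2 length-2 ranges for the two parameters.
#' @param data observation data frame containing `data_type`.
#' @param data_type the fitted data type (`"od_wt_only"`,
#'   `"od_coculture"` or `"freq_protease_deficient"`).
#' @param resolution grid points per axis (>= 2); classic maps use 41
#'   equidistant values.
#' @param base a [model_parameters()] object.
#' @param E0 initial enzyme concentration.
#' @param schedules simulation protocols.
#' @return A data frame `param1_value`, `param2_value`, `rmse`, `sign`,
#'   `status`, in row-major (param2 fastest) order, with attribute
#'   `minimum` giving the coordinates of the lowest-RMSE cell.
#' @export
pairwise_rmse_map <- function(param1, param2, range1, range2, data,
                              data_type = c("od_wt_only", "od_coculture",
                                            "freq_protease_deficient"),
                              resolution = 41,
                              base = model_parameters(), E0 = 3.00e-6,
                              schedules = default_schedules()) {
  data_type <- match.arg(data_type)
  stopifnot(resolution >= 2, length(range1) == 2, length(range2) == 2)
  obs <- data[data$data_type == data_type & !is.na(data$value), ,
              drop = FALSE]
  if (!nrow(obs)) stop("no observations of data_type ", data_type)
  v1 <- seq(range1[1], range1[2], length.out = resolution)
  v2 <- seq(range2[1], range2[2], length.out = resolution)
  scenario <- if (data_type == "od_wt_only") "wt_only" else "coculture"
  sched <- if (scenario == "wt_only") schedules$wt else schedules$co
  grid <- expand.grid(param2_value = v2, param1_value = v1)[, 2:1]
  n <- nrow(grid)
  rmse_v <- rep(NA_real_, n); sign_v <- rep(NA_real_, n)
  status <- rep("ok", n)
  set_par <- function(p, e0, nm, v) {
    if (nm == "E0") list(p = p, e0 = v)
    else { p[[nm]] <- v; list(p = p, e0 = e0) }
  }
  for (i in seq_len(n)) {
    s <- set_par(base, E0, param1, grid$param1_value[i])
    s <- set_par(s$p, s$e0, param2, grid$param2_value[i])
    cell <- try({
      pp <- s$p
      validate_parameters(pp)
      traj <- simulate_chemostat(pp, sched,
                                 initial_state(scenario, pp, s$e0),
                                 scenario = scenario)
      sim <- simulated_series(list(wt = traj, co = traj), data_type)
      resid <- unlist(lapply(split(obs, obs$replicate), function(rd) {
        approx(sim$time_h, sim$value, xout = rd$time_h,
               ties = "ordered")$y - rd$value
      }))
      list(rmse = rmse(sim, obs),
           sign = if (mean(resid, na.rm = TRUE) > 0) 1 else -1)
    }, silent = TRUE)
    if (inherits(cell, "try-error")) {
      status[i] <- "failed"
    } else {
      rmse_v[i] <- cell$rmse; sign_v[i] <- cell$sign
    }
  }
  out <- cbind(grid, rmse = rmse_v, sign = sign_v, status = status)
  ok <- which(status == "ok")
  if (length(ok)) {
    best <- ok[which.min(rmse_v[ok])]
    attr(out, "minimum") <- c(param1_value = grid$param1_value[best],
                              param2_value = grid$param2_value[best],
                              rmse = rmse_v[best])
  }
  out
}
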