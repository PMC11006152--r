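# Conversion of simulated states into experimentally measured quantities,
# and the derived fitness/saturation formulas.

# g dry weight per litre corresponding to one OD600 unit
OD_FACTOR <- 0.48

#' Observation series container
#'
#' One experimental or synthetic time series: optical density (OD600) or a
#' phenotype frequency (percent), tagged with its data type and replicate.
#'
#' @param time_h sample times (h), t = 0 at flow start.
#' @param value OD600 units or percent, depending on `data_type`.
#' @param data_type one of `"od_wt_only"`, `"od_coculture"`,
#'   `"freq_protease_deficient"`, `"freq_antibiotic_resistant"`.
#' @param replicate replicate identifier.
#' @return A data frame with class `observation_series`.
#' @export
observation_series <- function(time_h, value, data_type, replicate = "1") {
  allowed <- c("od_wt_only", "od_coculture", "freq_protease_deficient",
               "freq_antibiotic_resistant")
  if (!all(data_type %in% allowed)) {
    stop("unknown data_type; allowed: ", paste(allowed, collapse = ", "))
  }
  v <- value[!is.na(value)]
  if (any(v < 0)) stop("observations must be non-negative")
  if (any(grepl("^freq", data_type)) && any(v > 100)) {
    stop("frequencies must lie in [0, 100] percent")
  }
  structure(data.frame(time_h = time_h, value = value,
                       data_type = data_type,
                       replicate = as.character(replicate),
                       stringsAsFactors = FALSE),
            class = c("observation_series", "data.frame"))
}

#' Convert biomass to optical density (and back)
#'
#' Uses the fixed conversion 0.48 g dry weight/l per OD600 unit, derived
#' from the paired calibration values of the study system (0.0240 g/l at
#' OD 0.05).
#'
#' @param biomass biomass (g dry weight/l), non-negative.
#' @param od optical density (OD600), non-negative.
#' @param factor conversion factor (g dry weight/l per OD unit).
#' @return `biomass_to_od()`: OD600; `od_to_biomass()`: g dry weight/l.
#' @examples
#' biomass_to_od(0.045)  # QS threshold in OD units
#' @export
biomass_to_od <- function(biomass, factor = OD_FACTOR) {
  if (any(!is.finite(biomass)) || any(biomass < 0)) {
    stop("biomass must be finite and non-negative")
  }
  biomass / factor
}

#' @rdname biomass_to_od
#' @export
od_to_biomass <- function(od, factor = OD_FACTOR) {
  if (any(!is.finite(od)) || any(od < 0)) {
    stop("optical density must be finite and non-negative")
  }
  od * factor
}

#' Total optical density along a trajectory
#'
#' @param traj a `chemostat_trajectory`.
#' @return Numeric vector of total OD600 (all biomass classes).
#' @export
od600_total <- function(traj) {
  X3 <- if ("X3" %in% names(traj)) traj$X3 else 0
  biomass_to_od(traj$X1 + traj$X2 + X3)
}

#' Cheater frequency along a base-model trajectory
#'
#' Percent cheaters `100 * X2 / (X1 + X2)`. In the base model this is
#' non-decreasing in time, because the per-capita growth gap between
#' cheater and cooperator is `Q(X1) F(P) >= 0`. Below the biomass floor
#' the frequency is reported missing rather than 0/0.
#'
#' @param traj a `chemostat_trajectory` from the base model.
#' @param floor total-biomass floor (g dry weight/l).
#' @return An [observation_series()] with
#'   `data_type = "freq_protease_deficient"`.
#' @export
cheater_frequency <- function(traj, floor = 1e-12) {
  total <- traj$X1 + traj$X2
  value <- ifelse(total >= floor, 100 * traj$X2 / total, NA_real_)
  observation_series(traj$time_h, value, "freq_protease_deficient", "sim")
}

#' Closed-form saturation prediction for the cheater frequency
#'
#' Along any base-model solution the cheater frequency
#' `R = X2 / (X1 + X2)` obeys
#' `R(t) = R(0) e^{I(t)} / (1 - R(0) + R(0) e^{I(t)})` with
#' `I(t) = \int_0^t Q(X1(s)) F(P(s)) ds`, and approaches a constant
#' limit `c` with `0 < c <= 1` as the cooperator density falls below the
#' QS threshold and the selection gradient vanishes. The integral is
#' evaluated by the trapezoid rule on the trajectory grid (accuracy is
#' controlled by grid density), starting from the first sample at
#' `t >= 0`.
#'
#' @param traj a `chemostat_trajectory` from the base model.
#' @param params model parameters; default taken from the trajectory.
#' @return An [observation_series()] over the chemostat phase with the
#'   predicted frequency (percent).
#' @export
saturation_prediction <- function(traj, params = attr(traj, "params")) {
  keep <- traj$time_h >= 0
  if (!any(keep)) stop("trajectory has no chemostat-phase samples")
  tt <- traj$time_h[keep]
  X1 <- traj$X1[keep]; X2 <- traj$X2[keep]; P <- traj$P[keep]
  A <- hill_burden(X1, params) * monod_growth(P, params)
  I <- c(0, cumsum(diff(tt) * (head(A, -1) + tail(A, -1)) / 2))
  if (any(!is.finite(I))) stop("non-finite selection integral")
  R0 <- X2[1] / (X1[1] + X2[1])
  eI <- exp(I)
  R <- R0 * eI / (1 - R0 + R0 * eI)
  observation_series(tt, 100 * R, "freq_protease_deficient", "sim")
}

#' Absolute fitness from initial and final cell densities
#'
#' Natural log of the ratio of final to initial cell density.
#'
#' @param n_initial,n_final cell densities (both > 0, same units).
#' @return Dimensionless log fold-growth.
#' @examples
#' absolute_fitness(1e6, 1e7)  # ln(10)
#' @export
absolute_fitness <- function(n_initial, n_final) {
  if (any(n_initial <= 0) || any(n_final <= 0)) {
    stop("cell densities must be strictly positive")
  }
  log(n_final / n_initial)
}

#' Relative fitness of a mutant versus the wild type
#'
#' Ratio of the mutant's to the wild type's absolute fitness over the same
#' competition period. Values above 1 mean the mutant out-grew the WT. The
#' ratio is invariant to a common rescaling of all four densities.
#'
#' @param mutant_initial,mutant_final mutant cell densities (> 0).
#' @param wt_initial,wt_final wild-type cell densities (> 0).
#' @return Dimensionless fitness ratio.
#' @examples
#' relative_fitness(1e6, 4e7, 1e6, 1e7)  # ln(40)/ln(10)
#' @export
relative_fitness <- function(mutant_initial, mutant_final,
                             wt_initial, wt_final) {
  wt <- absolute_fitness(wt_initial, wt_final)
  if (any(wt == 0)) {
    stop("wild-type absolute fitness is zero; relative fitness undefined")
  }
  absolute_fitness(mutant_initial, mutant_final) / wt
}

#' Doubling time at steady state
#'
#' At chemostat steady state the net growth rate balances the dilution
#' rate, so the population doubling time is `ln(2) / D`.
#'
#' @param D dilution rate (1/h), > 0.
#' @return Doubling time (h).
#' @examples
#' doubling_time(0.12)
#' @export
doubling_time <- function(D) {
  if (any(!is.finite(D)) || any(D <= 0)) {
    stop("dilution rate D must be strictly positive")
  }
  log(2) / D
}

#' Dilution rate from flow rate and culture volume
#'
#' @param flow_ml_per_h pump flow rate (ml/h).
#' @param volume_ml culture volume (ml).
#' @return Dilution rate (1/h).
#' @examples
#' dilution_rate(12, 100)
#' @export
dilution_rate <- function(flow_ml_per_h, volume_ml) {
  if (any(flow_ml_per_h < 0) || any(volume_ml <= 0)) {
    stop("flow must be >= 0 and volume > 0")
  }
  flow_ml_per_h / volume_ml
}

#' Detect a steady state in an observation series
#'
#' The series is declared steady when the relative spread
#' `(max - min) / mean` of its values inside the trailing window is below
#' `tol`. The defaults (48 h window, 2 percent) match the roughly daily
#' sampling cadence of chemostat experiments.
#'
#' @param series an [observation_series()] or data frame with `time_h`
#'   and `value`.
#' @param window trailing window length (h).
#' @param tol relative tolerance.
#' @return A list with `steady` (logical) and `level` (window mean).
#' @export
detect_steady_state <- function(series, window = 48, tol = 0.02) {
  if (!nrow(series)) stop("empty series")
  if (diff(range(series$time_h)) < window) {
    stop("series shorter than the steady-state window")
  }
  w <- series$value[series$time_h >= max(series$time_h) - window]
  level <- mean(w)
  steady <- if (level <= 0) all(w == 0) else (max(w) - min(w)) / level < tol
  list(steady = steady, level = level)
}

#' Detect washout in an observation series
#'
#' @param series an [observation_series()] or data frame with `value`.
#' @param floor detection floor; final values below it count as washout.
#' @return Logical.
#' @export
detect_washout <- function(series, floor = 0.001) {
  if (!nrow(series)) stop("empty series")
  series$value[nrow(series)] < floor
}

# Simulated counterpart of a measured data type, as an observation series.
simulated_series <- function(sims, data_type) {
  switch(data_type,
    od_wt_only = observation_series(sims$wt$time_h, od600_total(sims$wt),
                                    "od_wt_only", "sim"),
    od_coculture = observation_series(sims$co$time_h, od600_total(sims$co),
                                      "od_coculture", "sim"),
    freq_protease_deficient = cheater_frequency(sims$co),
    stop("no simulated counterpart for data_type ", data_type))
}
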