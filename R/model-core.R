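# Base five-state chemostat model: auxiliary rate functions, the ODE
# right-hand side, and the batch-then-chemostat simulation protocol.

#' Quorum-sensing metabolic burden (Hill function)
#'
#' Fraction of metabolic energy a cooperator spends on protease
#' production, `Q(X1) = q * X1^n / (X1^n + QS_min^n)`. It is zero in the
#' absence of cooperators, rises switch-like once the cooperator density
#' passes `QS_min`, and saturates at the maximal burden `q`. The
#' degenerate case `QS_min = 0` (reached only in extended sensitivity
#' scans) uses the continuous extension `Q(0) = 0`, `Q(X1 > 0) = q`.
#'
#' @param X1 cooperator biomass (g dry weight/l), non-negative; vectorized.
#' @param params a [model_parameters()] object.
#' @return Burden fraction in `[0, q]`.
#' @examples
#' hill_burden(0.09, model_parameters())
#' @export
hill_burden <- function(X1, params = model_parameters()) {
  if (any(!is.finite(X1)) || any(X1 < 0)) {
    stop("cooperator biomass X1 must be finite and non-negative")
  }
  if (params$QS_min <= 0) {
    return(ifelse(X1 > 0, params$q, 0))
  }
  xn <- X1^params$n
  out <- params$q * xn / (xn + params$QS_min^params$n)
  out[X1 == 0] <- 0
  out
}

#' Monod growth rate
#'
#' Per-capita growth rate on the digestion product,
#' `F(P) = mu_max * P / (K_S + P)`: zero without product, half-maximal at
#' `P = K_S`, saturating at `mu_max`.
#'
#' @param P product concentration (mmol/l), non-negative; vectorized.
#' @param params a [model_parameters()] object.
#' @return Growth rate (1/h).
#' @examples
#' monod_growth(0.840, model_parameters())  # half-maximal
#' @export
monod_growth <- function(P, params = model_parameters()) {
  if (any(!is.finite(P)) || any(P < 0)) {
    stop("product concentration P must be finite and non-negative")
  }
  params$mu_max * P / (params$K_S + P)
}

#' Michaelis-Menten substrate cleavage rate
#'
#' Enzymatic proteolysis rate `G(S, E) = k_cat * E * S / (K_M + S)`:
#' linear in the enzyme concentration and saturating in the substrate.
#'
#' @param S substrate concentration (mmol/l), non-negative.
#' @param E enzyme concentration (mmol/l), non-negative.
#' @param params a [model_parameters()] object.
#' @return Cleavage rate (mmol/(l h)).
#' @examples
#' cleavage_rate(0.210, 3e-6, model_parameters())
#' @export
cleavage_rate <- function(S, E, params = model_parameters()) {
  if (any(!is.finite(S)) || any(S < 0)) {
    stop("substrate concentration S must be finite and non-negative")
  }
  if (any(!is.finite(E)) || any(E < 0)) {
    stop("enzyme concentration E must be finite and non-negative")
  }
  params$k_cat * E * S / (params$K_M + S)
}

#' Right-hand side of the base five-state chemostat system
#'
#' Time derivatives of substrate, product, enzyme, cooperator and cheater
#' concentrations at a given state:
#' \deqn{\dot S = D (S^0 - S) - G(S, E)}
#' \deqn{\dot P = \sigma G(S, E) - (X_1 + X_2) F(P) / \gamma - D P}
#' \deqn{\dot E = \eta Q(X_1) X_1 F(P) - D E}
#' \deqn{\dot X_1 = X_1 ((1 - Q(X_1)) F(P) - D)}
#' \deqn{\dot X_2 = X_2 (F(P) - D)}
#' The effective dilution `D_effective` is zero during the batch phase and
#' `params$D` during the chemostat phase. This R implementation mirrors
#' the compiled code used by [simulate_chemostat()] and serves direct
#' evaluation and testing.
#'
#' @param state named state vector as from [chemostat_state()].
#' @param params a [model_parameters()] object.
#' @param D_effective effective dilution rate for the current phase (1/h).
#' @return Named vector of derivatives.
#' @export
base_rhs <- function(state, params = model_parameters(),
                     D_effective = params$D) {
  if (any(!is.finite(state))) stop("state must be finite")
  if (any(state < 0)) stop("state must be non-negative")
  S <- state[["S"]]; P <- state[["P"]]; E <- state[["E"]]
  X1 <- state[["X1"]]; X2 <- state[["X2"]]
  Q <- hill_burden(X1, params)
  F_ <- monod_growth(P, params)
  G <- cleavage_rate(S, E, params)
  c(S = D_effective * (params$S0 - S) - G,
    P = params$sigma * G - (X1 + X2) * F_ / params$gamma - D_effective * P,
    E = params$eta * Q * X1 * F_ - D_effective * E,
    X1 = X1 * ((1 - Q) * F_ - D_effective),
    X2 = X2 * (F_ - D_effective))
}

# Parameter vector in the order the compiled derivatives expect.
pack_parms <- function(params, D_effective, alpha = 0, mu_max_2 = 0,
                       variant = 0) {
  c(D_effective, params$S0, params$mu_max, params$k_cat, params$K_S,
    params$K_M, params$eta, params$gamma, params$sigma, params$q,
    params$QS_min, params$n, alpha, mu_max_2, variant)
}

# Two-phase integration (batch then chemostat) on the compiled RHS.
# `func` is the name of the compiled derivative routine.
integrate_protocol <- function(y0, schedule, params, func,
                               alpha = 0, mu_max_2 = 0, variant = 0,
                               rtol = 1e-8, atol = 1e-10) {
  times <- schedule$sample_times
  t_batch <- times[times < 0]
  t_chemo <- times[times >= 0]

  run <- function(y, tt, Deff) {
    pv <- pack_parms(params, Deff, alpha, mu_max_2, variant)
    out <- try(deSolve::lsoda(y, tt, func = func, parms = pv,
                              dllname = "chemocoop",
                              initfunc = "chemocoop_init",
                              rtol = rtol, atol = atol), silent = TRUE)
    if (inherits(out, "try-error") ||
        nrow(out) < length(tt) || any(!is.finite(out))) {
      stop(simpleError(paste0(
        "ODE integration failed for parameter set: ",
        paste(sprintf("%s=%g", names(unlist(params)), unlist(params)),
              collapse = ", "))))
    }
    out
  }

  y0 <- as.numeric(y0)
  names(y0) <- if (variant > 0) c("S", "P", "E", "X1", "X2", "X3")
               else c("S", "P", "E", "X1", "X2")

  rows <- list()
  if (schedule$batch_hours > 0) {
    # integrate batch from -batch_hours to 0 even if no negative samples
    tt <- unique(c(-schedule$batch_hours, t_batch, 0))
    ob <- run(y0, tt, 0)
    keep <- ob[, "time"] %in% t_batch
    rows$batch <- ob[keep, , drop = FALSE]
    y0 <- ob[nrow(ob), -1]
  }
  if (length(t_chemo)) {
    if (max(t_chemo) == 0) {
      # flow never runs: the t = 0 sample is the batch end state
      rows$chemo <- matrix(c(0, y0), nrow = 1,
                           dimnames = list(NULL, c("time", names(y0))))
    } else {
      tt <- unique(c(0, t_chemo))
      oc <- run(y0, tt, params$D)
      keep <- oc[, "time"] %in% t_chemo
      rows$chemo <- oc[keep, , drop = FALSE]
    }
  }
  out <- do.call(rbind, rows)
  # clip solver undershoots just below zero
  state_cols <- setdiff(colnames(out), "time")
  m <- out[, state_cols, drop = FALSE]
  m[m < 0 & m > -1e-8] <- 0
  if (any(m < 0)) {
    stop("integration produced states below the clipping tolerance")
  }
  out[, state_cols] <- m
  df <- as.data.frame(out)
  names(df)[1] <- "time_h"
  rownames(df) <- NULL
  df
}

#' Simulate the batch-then-chemostat protocol of the base model
#'
#' Integrates the five-state system first in batch mode (dilution 0) and
#' then in chemostat mode (dilution `params$D`), reporting the state on
#' the schedule's sample grid. Time zero is the start of flow. A
#' stiff-capable solver (lsoda) is used with relative tolerance `1e-8`
#' and absolute tolerance `1e-10`; components within `1e-8` below zero
#' are clipped to zero.
#'
#' @param params a [model_parameters()] object.
#' @param schedule a [culture_schedule()]; default 32 h batch + 192 h
#'   chemostat (the WT-only protocol; cocultures use 55 h batch).
#' @param initial initial state, as from [initial_state()].
#' @param scenario label stored with the trajectory, `"wt_only"` or
#'   `"coculture"`.
#' @return A `chemostat_trajectory`: a data frame with columns `time_h`,
#'   `S`, `P`, `E`, `X1`, `X2` and attributes `params`, `schedule`,
#'   `scenario`.
#' @examples
#' traj <- simulate_chemostat(schedule = culture_schedule(32, 48))
#' tail(traj, 2)
#' @export
simulate_chemostat <- function(params = model_parameters(),
                               schedule = culture_schedule(32, 192),
                               initial = initial_state("wt_only", params),
                               scenario = c("wt_only", "coculture")) {
  scenario <- match.arg(scenario)
  validate_parameters(params)
  if (length(initial) != 5) stop("base model requires a 5-component state")
  df <- integrate_protocol(initial, schedule, params, "chemocoop_base")
  structure(df, class = c("chemostat_trajectory", "data.frame"),
            params = params, schedule = schedule, scenario = scenario)
}

#' @export
print.chemostat_trajectory <- function(x, ...) {
  cat(sprintf("Chemostat trajectory (%s), %d samples, t in [%g, %g] h\n",
              attr(x, "scenario"), nrow(x), min(x$time_h), max(x$time_h)))
  print.data.frame(utils::tail(as.data.frame(x), 3), ...)
  invisible(x)
}
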