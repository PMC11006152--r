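# Six-state model variants in which a faster-growing mutant X3 arises by
# mutation from either the cheater or the cooperator.

#' Parameters for the evolved-mutant model variants
#'
#' Extends the base model with an evolved mutant `X3` that arises from its
#' parent at mutation rate `alpha` and grows with Monod rate
#' `F2(P) = mu_max_2 * P / (K_S + P)`. Three variants are supported:
#' * `"cheater_from_lasR"` - a faster-growing, protease-deficient,
#'   antibiotic-resistant mutant derived from the marked cheater;
#' * `"cheater_from_WT"` - a faster-growing, protease-deficient,
#'   antibiotic-sensitive mutant derived from the cooperator;
#' * `"cooperator_from_WT"` - a faster-growing protease producer derived
#'   from the cooperator (it contributes to quorum sensing and enzyme
#'   production together with `X1`).
#'
#' @param base a [model_parameters()] object.
#' @param alpha mutation rate (1/h), >= 0. Biologically plausible values
#'   lie in `[1e-10, 1e-4]`; zero is allowed and reduces the system to the
#'   base model.
#' @param mu_max_2 maximal growth rate of the evolved mutant (1/h), > 0.
#' @param variant one of the three variant labels above.
#' @return An object of class `evolved_parameters`.
#' @examples
#' evolved_parameters(alpha = 1e-4, mu_max_2 = 3.8,
#'                    variant = "cheater_from_lasR")
#' @export
evolved_parameters <- function(base = model_parameters(), alpha,
                               mu_max_2,
                               variant = c("cheater_from_lasR",
                                           "cheater_from_WT",
                                           "cooperator_from_WT")) {
  variant <- match.arg(variant)
  validate_parameters(base)
  stopifnot(is.numeric(alpha), length(alpha) == 1, is.finite(alpha),
            alpha >= 0, is.numeric(mu_max_2), length(mu_max_2) == 1,
            is.finite(mu_max_2), mu_max_2 > 0)
  structure(list(base = base, alpha = alpha, mu_max_2 = mu_max_2,
                 variant = variant),
            class = "evolved_parameters")
}

variant_code <- function(variant) {
  match(variant, c("cheater_from_lasR", "cheater_from_WT",
                   "cooperator_from_WT"))
}

#' Right-hand side of the evolved-mutant systems
#'
#' Time derivatives of the six-state systems. In all variants the mutant
#' `X3` receives an inflow `alpha * X_parent` while the parent loses the
#' same flux, so total biomass dynamics are unchanged by the relabeling.
#' In the `"cooperator_from_WT"` variant the QS burden and enzyme
#' production are evaluated on the combined producer density
#' `Q(X1 + X3)`, with enzyme term
#' `eta * Q(X1 + X3) * (X1 * F(P) + X3 * F2(P))`.
#' With `alpha = 0` and `X3 = 0` every variant reduces exactly to
#' [base_rhs()] on the shared components.
#'
#' @param state named 6-component state (`S`, `P`, `E`, `X1`, `X2`, `X3`).
#' @param params an [evolved_parameters()] object.
#' @param D_effective effective dilution rate for the current phase (1/h).
#' @return Named vector of derivatives.
#' @export
variant_rhs <- function(state, params, D_effective = params$base$D) {
  stopifnot(inherits(params, "evolved_parameters"))
  if (any(!is.finite(state))) stop("state must be finite")
  if (any(state < 0)) stop("state must be non-negative")
  b <- params$base
  S <- state[["S"]]; P <- state[["P"]]; E <- state[["E"]]
  X1 <- state[["X1"]]; X2 <- state[["X2"]]; X3 <- state[["X3"]]
  a <- params$alpha
  F_ <- monod_growth(P, b)
  F2 <- params$mu_max_2 * P / (b$K_S + P)
  G <- cleavage_rate(S, E, b)
  dS <- D_effective * (b$S0 - S) - G
  dP <- b$sigma * G - ((X1 + X2) * F_ + X3 * F2) / b$gamma -
    D_effective * P
  if (params$variant == "cheater_from_lasR") {
    Q <- hill_burden(X1, b)
    dE <- b$eta * Q * X1 * F_ - D_effective * E
    dX1 <- X1 * ((1 - Q) * F_ - D_effective)
    dX2 <- X2 * (F_ - D_effective - a)
    dX3 <- X3 * (F2 - D_effective) + a * X2
  } else if (params$variant == "cheater_from_WT") {
    Q <- hill_burden(X1, b)
    dE <- b$eta * Q * X1 * F_ - D_effective * E
    dX1 <- X1 * ((1 - Q) * F_ - D_effective - a)
    dX2 <- X2 * (F_ - D_effective)
    dX3 <- X3 * (F2 - D_effective) + a * X1
  } else {
    Q <- hill_burden(X1 + X3, b)
    dE <- b$eta * Q * (X1 * F_ + X3 * F2) - D_effective * E
    dX1 <- X1 * ((1 - Q) * F_ - D_effective - a)
    dX2 <- X2 * (F_ - D_effective)
    dX3 <- X3 * ((1 - Q) * F2 - D_effective) + a * X1
  }
  c(S = dS, P = dP, E = dE, X1 = dX1, X2 = dX2, X3 = dX3)
}

#' Simulate an evolved-mutant model variant
#'
#' Batch-then-chemostat integration of the six-state system selected by
#' `params$variant`, with the same solver settings as
#' [simulate_chemostat()]. By default the mutant is absent initially
#' (`X3 = 0`) and arises only through mutation.
#'
#' @param params an [evolved_parameters()] object.
#' @param schedule a [culture_schedule()]; cocultures use 55 h batch.
#' @param initial 6-component initial state; defaults to the coculture
#'   initial state with `X3 = 0`.
#' @param scenario label stored with the trajectory.
#' @return A `chemostat_trajectory` with an `X3` column and attribute
#'   `variant`.
#' @export
simulate_evolved <- function(params,
                             schedule = culture_schedule(55, 192),
                             initial = NULL,
                             scenario = "coculture") {
  stopifnot(inherits(params, "evolved_parameters"))
  if (is.null(initial)) {
    y <- initial_state("coculture", params$base)
    initial <- chemostat_state(y[["S"]], y[["P"]], y[["E"]], y[["X1"]],
                               y[["X2"]], X3 = 0)
  }
  if (length(initial) != 6) {
    stop("evolved model requires a 6-component state (S,P,E,X1,X2,X3)")
  }
  df <- integrate_protocol(initial, schedule, params$base,
                           "chemocoop_evolved",
                           alpha = params$alpha,
                           mu_max_2 = params$mu_max_2,
                           variant = variant_code(params$variant))
  structure(df, class = c("chemostat_trajectory", "data.frame"),
            params = params$base, evolved_params = params,
            schedule = schedule, scenario = scenario,
            variant = params$variant)
}

#' Phenotype frequencies implied by a trajectory
#'
#' Maps subpopulation biomasses onto the two plate-assay phenotypes,
#' protease deficiency (PD, skim-milk assay) and antibiotic resistance
#' (AR, trimethoprim assay):
#' * `cheater_from_lasR`: the mutant keeps the resistance marker, so
#'   PD = AR = `(X2 + X3) / total`;
#' * `cheater_from_WT`: the mutant is unmarked, so
#'   PD = `(X2 + X3) / total` but AR = `X2 / total`;
#' * `cooperator_from_WT`: the mutant produces enzyme and is unmarked, so
#'   PD = AR = `X2 / total`.
#' Base-model trajectories (no `X3`) give PD = AR = `X2 / total`.
#'
#' @param traj a `chemostat_trajectory`.
#' @param variant variant label; defaults to the trajectory's own.
#' @param floor total-biomass floor (g dry weight/l) below which the
#'   frequency is reported as `NA` rather than 0/0.
#' @return A data frame with columns `time_h`, `pd_percent`, `ar_percent`.
#' @export
phenotype_frequencies <- function(traj, variant = attr(traj, "variant"),
                                  floor = 1e-12) {
  X3 <- if ("X3" %in% names(traj)) traj$X3 else 0
  total <- traj$X1 + traj$X2 + X3
  ok <- total >= floor
  frac <- function(num) ifelse(ok, 100 * num / total, NA_real_)
  if (is.null(variant) || !("X3" %in% names(traj))) {
    pd <- ar <- frac(traj$X2)
  } else if (variant == "cheater_from_lasR") {
    pd <- ar <- frac(traj$X2 + X3)
  } else if (variant == "cheater_from_WT") {
    pd <- frac(traj$X2 + X3)
    ar <- frac(traj$X2)
  } else if (variant == "cooperator_from_WT") {
    pd <- ar <- frac(traj$X2)
  } else {
    stop("unknown variant: ", variant)
  }
  data.frame(time_h = traj$time_h, pd_percent = pd, ar_percent = ar)
}
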