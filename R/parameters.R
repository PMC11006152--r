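# Parameter and schedule containers for the chemostat model.

#' Model parameters for the chemostat cooperation model
#'
#' Creates a validated set of rate constants and quorum-sensing (QS)
#' parameters for the five-state chemostat model. The defaults are the
#' best-fit values obtained by calibrating the model against WT-only
#' density, coculture density and protease-deficiency frequency series
#' from continuous cultures of *Pseudomonas aeruginosa* on gelatin.
#'
#' @param S0 inflow substrate concentration (mmol/l).
#' @param D dilution rate (1/h); flow rate divided by culture volume.
#' @param mu_max maximal per-capita growth rate (1/h).
#' @param k_cat enzyme turnover number (1/h).
#' @param K_S product concentration at half-maximal growth (mmol/l).
#' @param K_M substrate concentration at half-maximal cleavage (mmol/l).
#' @param eta enzyme produced per unit biomass (mmol per g dry weight).
#' @param gamma product-to-biomass yield (g dry weight/mmol).
#' @param sigma cleavage products generated per substrate molecule.
#' @param q maximal metabolic burden of enzyme production, in `[0, 1]`.
#' @param QS_min cooperator density at half-maximal QS activation
#'   (g dry weight/l).
#' @param n Hill coefficient of the QS response (>= 1).
#'
#' @return An object of class `model_parameters` (a named list).
#' @examples
#' p <- model_parameters()
#' p$q
#' @export
model_parameters <- function(S0 = 0.210, D = 0.121, mu_max = 1.38,
                             k_cat = 480, K_S = 0.840, K_M = 0.068,
                             eta = 620e-6, gamma = 0.0423, sigma = 40.0,
                             q = 0.610, QS_min = 0.045, n = 2) {
  p <- list(S0 = S0, D = D, mu_max = mu_max, k_cat = k_cat, K_S = K_S,
            K_M = K_M, eta = eta, gamma = gamma, sigma = sigma, q = q,
            QS_min = QS_min, n = n)
  validate_parameters(p)
  structure(p, class = "model_parameters")
}

#' Validate a model parameter set
#'
#' Checks positivity constraints: all rates and concentrations must be
#' strictly positive, except the dilution rate `D` (>= 0, since batch mode
#' sets it to zero) and the burden `q` (in `[0, 1]`).
#'
#' @param p a list with the fields of [model_parameters()].
#' @return `p`, invisibly, if valid; otherwise an error.
#' @export
validate_parameters <- function(p) {
  need <- c("S0", "D", "mu_max", "k_cat", "K_S", "K_M", "eta", "gamma",
            "sigma", "q", "QS_min", "n")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    stop("missing parameter field(s): ", paste(miss, collapse = ", "))
  }
  vals <- unlist(p[need])
  if (any(!is.finite(vals))) {
    stop("non-finite parameter value(s): ",
         paste(need[!is.finite(vals)], collapse = ", "))
  }
  strict <- setdiff(need, c("D", "q", "QS_min"))
  bad <- strict[unlist(p[strict]) <= 0]
  if (length(bad)) {
    stop("parameter(s) must be strictly positive: ",
         paste(bad, collapse = ", "))
  }
  if (p$D < 0) stop("dilution rate D must be >= 0")
  # QS_min = 0 is a degenerate extended-scan case (burden jumps to q)
  if (p$QS_min < 0) stop("QS threshold QS_min must be >= 0")
  if (p$q < 0 || p$q > 1) stop("metabolic burden q must lie in [0, 1]")
  if (p$n < 1) stop("Hill coefficient n must be >= 1")
  invisible(p)
}

#' Estimated parameter ranges used for ensemble sampling
#'
#' Biologically estimated ranges for the parameters that are known only to
#' an interval (the others are single point estimates). These ranges bound
#' the random draws of the calibration pipeline and the property checks.
#'
#' @return A named list of length-2 numeric vectors `c(lower, upper)`,
#'   including the initial enzyme concentration `E0`.
#' @export
parameter_ranges <- function() {
  list(
    S0     = c(0.200, 0.250),
    E0     = c(0, 2.424e-5),
    k_cat  = c(40, 500),
    K_M    = c(0.0580, 0.0725),
    eta    = c(0, 126e-5),
    sigma  = c(36.0, 46.0),
    q      = c(0.0425, 0.625),
    QS_min = c(0.0447, 0.161)
  )
}

#' Culture schedule: batch phase followed by chemostat phase
#'
#' The culture is first grown in batch mode (dilution forced to zero) and
#' then switched to chemostat mode (dilution from the parameter set). Time
#' zero is the moment flow starts, so batch-phase times are negative.
#'
#' @param batch_hours duration of the batch phase (h, >= 0).
#' @param chemostat_hours duration of the chemostat phase (h, >= 0).
#' @param sample_times optional strictly increasing grid of report times
#'   (h), spanning `[-batch_hours, chemostat_hours]`. Defaults to an
#'   hourly grid.
#'
#' @return An object of class `culture_schedule`.
#' @examples
#' culture_schedule(32, 192)
#' @export
culture_schedule <- function(batch_hours, chemostat_hours,
                             sample_times = NULL) {
  stopifnot(is.numeric(batch_hours), batch_hours >= 0,
            is.numeric(chemostat_hours), chemostat_hours >= 0)
  if (is.null(sample_times)) {
    sample_times <- unique(c(seq(-batch_hours, 0, by = 1),
                             seq(0, chemostat_hours, by = 1)))
  }
  if (any(diff(sample_times) <= 0)) {
    stop("sample_times must be strictly increasing")
  }
  if (min(sample_times) < -batch_hours - 1e-9 ||
      max(sample_times) > chemostat_hours + 1e-9) {
    stop("sample_times must lie within [-batch_hours, chemostat_hours]")
  }
  structure(list(batch_hours = batch_hours,
                 chemostat_hours = chemostat_hours,
                 sample_times = sample_times),
            class = "culture_schedule")
}

#' Chemostat state vector
#'
#' Assembles and validates a state of the chemostat: substrate `S`,
#' product `P`, enzyme `E` (all mmol/l), cooperator `X1` and cheater `X2`
#' biomass (g dry weight/l), and optionally evolved-mutant biomass `X3`.
#'
#' @param S,P,E,X1,X2 non-negative state components.
#' @param X3 evolved-mutant biomass; `NULL` for the base five-state model.
#' @return A named numeric vector.
#' @export
chemostat_state <- function(S, P, E, X1, X2, X3 = NULL) {
  y <- c(S = S, P = P, E = E, X1 = X1, X2 = X2)
  if (!is.null(X3)) y <- c(y, X3 = X3)
  if (any(!is.finite(y))) stop("state components must be finite")
  if (any(y < 0)) {
    stop("state components must be non-negative: ",
         paste(names(y)[y < 0], collapse = ", "))
  }
  y
}

#' Default initial states for the two culture scenarios
#'
#' WT-only cultures start at a total optical density of 0.05 (0.0240 g dry
#' weight/l of cooperators); cocultures start at the same total density
#' with a 10 percent cheater fraction (0.0216 + 0.00240 g/l). The substrate
#' starts at the inflow concentration, the product at zero, and the enzyme
#' at a small seed concentration.
#'
#' @param scenario `"wt_only"` or `"coculture"`.
#' @param params a [model_parameters()] object; sets the initial substrate.
#' @param E0 initial enzyme concentration (mmol/l).
#' @param S_init initial substrate concentration; defaults to `params$S0`.
#' @return A named state vector as from [chemostat_state()].
#' @examples
#' initial_state("coculture")
#' @export
initial_state <- function(scenario = c("wt_only", "coculture"),
                          params = model_parameters(), E0 = 3.00e-6,
                          S_init = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(S_init)) S_init <- params$S0
  if (scenario == "wt_only") {
    chemostat_state(S = S_init, P = 0, E = E0, X1 = 0.0240, X2 = 0)
  } else {
    chemostat_state(S = S_init, P = 0, E = E0, X1 = 0.0216, X2 = 0.00240)
  }
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Chemostat model parameters:\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.culture_schedule <- function(x, ...) {
  cat(sprintf("Culture schedule: %g h batch, %g h chemostat, %d samples\n",
              x$batch_hours, x$chemostat_hours, length(x$sample_times)))
  invisible(x)
}
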