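# Shared fixtures: best-fit parameters, fast schedules, random draws.

best_fit <- model_parameters()

# coarse grids keep the unit tests fast; the solver steps adaptively so
# output density does not affect accuracy at the sampled times
fast_wt_schedule <- function(chemo = 192) {
  culture_schedule(32, chemo, unique(c(seq(-32, 0, 4), seq(0, chemo, 4))))
}
fast_co_schedule <- function(chemo = 192) {
  culture_schedule(55, chemo, unique(c(seq(-55, 0, 4), seq(0, chemo, 4))))
}

# dense chemostat grid for quadrature-sensitive checks
dense_co_schedule <- function(chemo = 192) {
  culture_schedule(55, chemo, unique(c(
    seq(-55, 0, 1), seq(0, 5, 0.002), seq(5, 30, 0.01),
    seq(30, 100, 0.05), seq(100, chemo, 0.1))))
}

sim_wt <- function(params = best_fit, E0 = 3e-6, chemo = 192) {
  simulate_chemostat(params, fast_wt_schedule(chemo),
                     initial_state("wt_only", params, E0))
}
sim_co <- function(params = best_fit, E0 = 3e-6, chemo = 192,
                   schedule = fast_co_schedule(chemo)) {
  simulate_chemostat(params, schedule,
                     initial_state("coculture", params, E0),
                     scenario = "coculture")
}

# one row of a sampling-scheme draw -> model_parameters + E0
params_from_draw <- function(d) {
  list(params = model_parameters(S0 = d$S0, D = d$D, mu_max = d$mu_max,
                                 k_cat = d$k_cat, K_S = d$K_S,
                                 K_M = d$K_M, eta = d$eta,
                                 gamma = d$gamma, sigma = d$sigma,
                                 q = d$q, QS_min = d$QS_min, n = d$n),
       E0 = d$E0)
}

# independent steady-state oracle for the WT-only culture: solves the
# algebraic fixed-point conditions by nested root-finding, without any
# time integration. The product balance can vanish at two cooperator
# densities (an unstable threshold and the stable upper state); the
# oracle returns the upper root.
wt_steady_state_oracle <- function(p) {
  residual <- function(X1) {
    Q <- p$q * X1^p$n / (X1^p$n + p$QS_min^p$n)
    F_ <- p$D / (1 - Q)
    if (F_ >= p$mu_max) return(NA_real_)
    P <- p$K_S * F_ / (p$mu_max - F_)
    E <- p$eta * Q * X1 * F_ / p$D
    g <- function(S) p$D * (p$S0 - S) - p$k_cat * E * S / (p$K_M + S)
    S <- uniroot(g, c(0, p$S0), tol = 1e-14)$root
    G <- p$k_cat * E * S / (p$K_M + S)
    p$sigma * G - X1 * F_ / p$gamma - p$D * P
  }
  grid <- seq(0.01, 1, by = 0.002)
  r <- vapply(grid, residual, numeric(1))
  flips <- which(!is.na(r[-1]) & !is.na(r[-length(r)]) &
                   r[-1] * r[-length(r)] < 0)
  stopifnot(length(flips) >= 1)
  i <- flips[length(flips)]
  uniroot(residual, grid[c(i, i + 1)], tol = 1e-12)$root
}
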