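test_that("Hill burden has the half-saturation, limit and boundary values", {
  p <- best_fit
  expect_identical(hill_burden(0, p), 0)
  expect_equal(hill_burden(p$QS_min, p), p$q / 2)
  # hand evaluation: 0.610 * 0.09^2 / (0.09^2 + 0.045^2)
  expect_equal(hill_burden(0.09, p), 0.488, tolerance = 1e-6)
  # strictly increasing, bounded by q
  x <- seq(0, 1, length.out = 200)
  qx <- hill_burden(x, p)
  expect_true(all(diff(qx) > 0))
  expect_true(all(qx <= p$q))
  # saturation limit
  expect_equal(hill_burden(1e4 * p$QS_min, p), p$q, tolerance = 1e-3)
  expect_error(hill_burden(-0.1, p), "non-negative")
  # degenerate QS_min = 0: continuous extension
  p0 <- model_parameters(QS_min = 0)
  expect_identical(hill_burden(0, p0), 0)
  expect_equal(hill_burden(1e-9, p0), p0$q)
})

test_that("Monod growth has the half-saturation and asymptote", {
  p <- best_fit
  expect_identical(monod_growth(0, p), 0)
  expect_equal(monod_growth(p$K_S, p), p$mu_max / 2)
  expect_equal(monod_growth(3 * p$K_S, p), 1.035)  # 1.38 * 3/4
  expect_equal(monod_growth(1e4 * p$K_S, p), p$mu_max, tolerance = 1e-3)
  expect_true(all(diff(monod_growth(seq(0, 5, 0.1), p)) > 0))
  expect_error(monod_growth(-1, p), "non-negative")
})

test_that("cleavage rate is linear in enzyme and saturating in substrate", {
  p <- best_fit
  expect_identical(cleavage_rate(0.5, 0, p), 0)
  expect_identical(cleavage_rate(0, 1e-5, p), 0)
  expect_equal(cleavage_rate(p$K_M, 2e-6, p), p$k_cat * 2e-6 / 2)
  # hand evaluation: 480 * 3e-6 * 0.210 / (0.068 + 0.210)
  expect_equal(cleavage_rate(0.210, 3.00e-6, p), 1.08777e-3,
               tolerance = 1e-5)
  expect_equal(cleavage_rate(0.1, 4e-6, p), 2 * cleavage_rate(0.1, 2e-6, p))
  expect_error(cleavage_rate(-1, 1e-6, p), "non-negative")
  expect_error(cleavage_rate(0.1, -1e-6, p), "non-negative")
})

test_that("base RHS balances inflow and outflow and enforces the domain", {
  p <- best_fit
  # sterile vessel at inflow concentration: nothing changes
  y0 <- chemostat_state(S = p$S0, P = 0, E = 0, X1 = 0, X2 = 0)
  expect_equal(unname(base_rhs(y0, p, p$D)), rep(0, 5))
  # sterile vessel below inflow concentration: only substrate rises
  y1 <- chemostat_state(S = p$S0 / 2, P = 0, E = 0, X1 = 0, X2 = 0)
  d1 <- base_rhs(y1, p, p$D)
  expect_gt(d1[["S"]], 0)
  expect_equal(unname(d1[c("P", "E", "X1", "X2")]), rep(0, 4))
  # batch mode: no dilution loss terms
  y2 <- chemostat_state(S = 0.1, P = 0.2, E = 1e-5, X1 = 0.05, X2 = 0.01)
  d_batch <- base_rhs(y2, p, 0)
  expect_equal(d_batch[["S"]], -cleavage_rate(0.1, 1e-5, p))
  expect_equal(d_batch[["X2"]], 0.01 * monod_growth(0.2, p))
  # per-capita growth gap equals the burden Q(X1) * F(P)
  y3 <- initial_state("coculture", p)
  y3[["P"]] <- 0.15
  d3 <- base_rhs(y3, p, p$D)
  gap <- d3[["X2"]] / y3[["X2"]] - d3[["X1"]] / y3[["X1"]]
  expect_equal(gap, hill_burden(y3[["X1"]], p) * monod_growth(0.15, p))
  expect_error(base_rhs(c(S = -1, P = 0, E = 0, X1 = 0, X2 = 0), p),
               "non-negative")
  expect_error(base_rhs(c(S = NaN, P = 0, E = 0, X1 = 0, X2 = 0), p),
               "finite")
})

test_that("WT-only culture reaches the steady state of the fixed-point
           oracle", {
  traj <- sim_wt(chemo = 300)
  od <- observation_series(traj$time_h, od600_total(traj), "od_wt_only")
  ss <- detect_steady_state(od, window = 48, tol = 0.02)
  expect_true(ss$steady)
  # independent algebraic fixed point (no time integration)
  x1_star <- wt_steady_state_oracle(best_fit)
  expect_equal(traj$X1[nrow(traj)], x1_star, tolerance = 1e-4)
})

test_that("coculture collapses under dilution but not in pure batch", {
  co <- sim_co()
  od <- od600_total(co)
  expect_lt(od[length(od)], 0.001)          # washout
  expect_gt(max(od[co$time_h <= 0]), 0.3)   # but substantial batch growth
  p0 <- model_parameters(D = 0)
  co0 <- sim_co(p0)
  expect_gt(tail(od600_total(co0), 1), 0.3) # no dilution, no collapse
})

test_that("batch phase is unaffected by what follows it", {
  sched_full <- culture_schedule(32, 64, unique(c(seq(-32, 0, 2),
                                                  seq(0, 64, 4))))
  sched_batch <- culture_schedule(32, 0, seq(-32, 0, 2))
  full <- simulate_chemostat(best_fit, sched_full)
  batch <- simulate_chemostat(best_fit, sched_batch)
  shared <- full[full$time_h <= 0, ]
  expect_equal(as.data.frame(batch), as.data.frame(shared),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("trajectories stay nonnegative and bounded across random
           parameter draws", {
  set.seed(401)
  draws <- sample_parameters(sampling_scheme("round1"), 25)
  for (i in seq_len(nrow(draws))) {
    s <- params_from_draw(draws[i, ])
    for (scen in c("wt_only", "coculture")) {
      sched <- if (scen == "wt_only") fast_wt_schedule()
               else fast_co_schedule()
      tr <- simulate_chemostat(s$params, sched,
                               initial_state(scen, s$params, s$E0),
                               scenario = scen)
      m <- as.matrix(tr[, c("S", "P", "E", "X1", "X2")])
      expect_true(all(is.finite(m)))
      expect_true(all(m >= 0))
      # crude mass-balance bound: substrate below inflow + initial,
      # biomass below total convertible nutrient
      expect_true(all(tr$S <= max(s$params$S0, tr$S[1]) + 1e-6))
      cap <- s$params$gamma * s$params$sigma *
        max(s$params$S0, tr$S[1]) * 10
      expect_true(all(tr$X1 + tr$X2 <= cap))
    }
  }
})

test_that("integration failures identify the offending parameter set", {
  sched <- culture_schedule(2, 0, c(-2, -1, 0))
  # overflow in the product balance breaks the step-size control
  bad <- model_parameters(sigma = 1e308)
  suppressWarnings(
    expect_error(simulate_chemostat(bad, sched,
                                    initial_state("wt_only", bad)),
                 "parameter set"))
})

test_that("schedule and state constructors reject malformed input", {
  expect_error(culture_schedule(-1, 10), ">= 0")
  expect_error(culture_schedule(10, 10, c(0, 0, 1)), "increasing")
  expect_error(chemostat_state(1, 1, 1, -0.1, 0), "non-negative")
  expect_error(model_parameters(q = 1.5), "q must lie")
  expect_error(model_parameters(mu_max = -1), "strictly positive")
})
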