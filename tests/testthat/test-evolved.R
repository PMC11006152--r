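test_that("alpha = 0 evolved systems reduce exactly to the base model", {
  sched <- fast_co_schedule(96)
  base <- sim_co(chemo = 96, schedule = sched)
  for (v in c("cheater_from_lasR", "cheater_from_WT",
              "cooperator_from_WT")) {
    ep <- evolved_parameters(best_fit, alpha = 0, mu_max_2 = 3.8,
                             variant = v)
    ev <- simulate_evolved(ep, sched)
    expect_true(all(ev$X3 == 0))
    for (col in c("S", "P", "E", "X1", "X2")) {
      expect_equal(ev[[col]], base[[col]], tolerance = 1e-7,
                   label = paste(v, col))
    }
  }
})

test_that("mutational flux cancels in the parent + mutant biomass sum", {
  set.seed(77)
  for (i in 1:25) {
    st <- chemostat_state(S = runif(1, 0, 0.25), P = runif(1, 0, 1),
                          E = runif(1, 0, 1e-4), X1 = runif(1, 0, 0.3),
                          X2 = runif(1, 0, 0.3), X3 = runif(1, 0, 0.3))
    a <- 10^runif(1, -10, -4)
    ep1 <- evolved_parameters(best_fit, a, 3.8, "cheater_from_lasR")
    d1 <- variant_rhs(st, ep1, 0.121)
    # relabeling-free growth of the cheater lineage (X2 + X3)
    F_ <- monod_growth(st[["P"]], best_fit)
    F2 <- 3.8 * st[["P"]] / (best_fit$K_S + st[["P"]])
    expect_equal(d1[["X2"]] + d1[["X3"]],
                 st[["X2"]] * (F_ - 0.121) + st[["X3"]] * (F2 - 0.121))
    ep2 <- evolved_parameters(best_fit, a, 3.8, "cheater_from_WT")
    d2 <- variant_rhs(st, ep2, 0.121)
    Q <- hill_burden(st[["X1"]], best_fit)
    expect_equal(d2[["X1"]] + d2[["X3"]],
                 st[["X1"]] * ((1 - Q) * F_ - 0.121) +
                   st[["X3"]] * (F2 - 0.121))
    ep3 <- evolved_parameters(best_fit, a, 3.8, "cooperator_from_WT")
    d3 <- variant_rhs(st, ep3, 0.121)
    Q3 <- hill_burden(st[["X1"]] + st[["X3"]], best_fit)
    expect_equal(d3[["X1"]] + d3[["X3"]],
                 st[["X1"]] * ((1 - Q3) * F_ - 0.121) +
                   st[["X3"]] * ((1 - Q3) * F2 - 0.121))
  }
})

test_that("compiled and R right-hand sides agree for all variants", {
  # the R implementation is the readable reference; the compiled code is
  # what simulate_evolved integrates
  sched <- culture_schedule(2, 2, c(-2, 0, 2))
  st <- chemostat_state(S = 0.2, P = 0.3, E = 2e-5, X1 = 0.1, X2 = 0.05,
                        X3 = 0.02)
  for (v in c("cheater_from_lasR", "cheater_from_WT",
              "cooperator_from_WT")) {
    ep <- evolved_parameters(best_fit, 1e-5, 4.0, v)
    # one tiny explicit-Euler step of the R RHS vs a tiny integration
    h <- 1e-6
    d <- variant_rhs(st, ep, 0)
    euler <- st + h * d
    tr <- simulate_evolved(ep, culture_schedule(h, 0, c(-h, 0)),
                           initial = st)
    expect_equal(unlist(tr[nrow(tr), c("S", "P", "E", "X1", "X2", "X3")]),
                 euler, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("a faster-growing lasR-derived cheater raises the
           protease-deficient frequency above the base prediction", {
  base_freq <- tail(cheater_frequency(sim_co())$value, 1)
  ep <- evolved_parameters(best_fit, alpha = 1e-4, mu_max_2 = 3.8,
                           variant = "cheater_from_lasR")
  ph <- phenotype_frequencies(simulate_evolved(ep, fast_co_schedule()))
  pd <- tail(ph$pd_percent[!is.na(ph$pd_percent)], 1)
  ar <- tail(ph$ar_percent[!is.na(ph$ar_percent)], 1)
  expect_gt(pd, base_freq)
  expect_equal(pd, ar)  # mutant keeps the resistance marker
})

test_that("a WT-derived cheater keeps protease-deficiency high while
           antibiotic resistance falls", {
  ep <- evolved_parameters(best_fit, alpha = 7e-7, mu_max_2 = 4.0,
                           variant = "cheater_from_WT")
  tr <- simulate_evolved(ep, fast_co_schedule())
  ph <- phenotype_frequencies(tr)
  ok <- !is.na(ph$pd_percent)
  pd <- ph$pd_percent[ok]; ar <- ph$ar_percent[ok]
  expect_gt(tail(pd, 1), 60)
  expect_lt(tail(ar, 1), tail(cheater_frequency(sim_co())$value, 1))
  # PD >= AR whenever the unmarked mutant is present
  x3 <- tr$X3[ok]
  expect_true(all(pd[x3 > 0] >= ar[x3 > 0]))
})

test_that("phenotype mapping follows the plate-assay logic", {
  toy <- data.frame(time_h = 0, X1 = 0.1, X2 = 0.1, X3 = 0.2)
  ph2 <- phenotype_frequencies(toy, variant = "cheater_from_WT")
  expect_equal(ph2$pd_percent, 75)
  expect_equal(ph2$ar_percent, 25)
  ph1 <- phenotype_frequencies(data.frame(time_h = 0, X1 = 0.2, X2 = 0.1,
                                          X3 = 0.1),
                               variant = "cheater_from_lasR")
  expect_equal(ph1$pd_percent, ph1$ar_percent)  # both marked phenotypes
  ph3 <- phenotype_frequencies(toy, variant = "cooperator_from_WT")
  expect_equal(ph3$pd_percent, 25)
  # no mutant present: all variants give X2 / total
  toy0 <- data.frame(time_h = 0, X1 = 0.3, X2 = 0.1, X3 = 0)
  for (v in c("cheater_from_lasR", "cheater_from_WT",
              "cooperator_from_WT")) {
    ph <- phenotype_frequencies(toy0, variant = v)
    expect_equal(ph$pd_percent, 25)
  }
  # below the biomass floor the frequency is missing, not 0/0
  tiny <- data.frame(time_h = 0, X1 = 1e-14, X2 = 1e-14, X3 = 0)
  expect_true(is.na(phenotype_frequencies(tiny,
                                          variant = "cheater_from_WT")$pd_percent))
})

test_that("evolved parameter validation rejects bad input", {
  expect_error(evolved_parameters(best_fit, -1e-5, 3.8,
                                  "cheater_from_lasR"))
  expect_error(evolved_parameters(best_fit, 1e-5, 0, "cheater_from_WT"))
  expect_error(evolved_parameters(best_fit, 1e-5, 3.8, "nonsense"))
})
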