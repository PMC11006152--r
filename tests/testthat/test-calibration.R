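test_that("parameter sampling respects supports and is reproducible", {
  sch2 <- sampling_scheme("round2")
  d <- sample_parameters(sch2, 500, seed = 42)
  expect_equal(nrow(d), 500)
  expect_true(all(d$sigma >= 36 & d$sigma <= 46))
  expect_true(all(d$k_cat >= 150 & d$k_cat <= 500))
  expect_true(all(d$eta >= 4e-4 & d$eta <= 126e-5))
  expect_true(all(d$q >= 0.0425 & d$q <= 0.625))
  expect_true(all(d$QS_min >= 0.0447 & d$QS_min <= 0.161))
  expect_true(all(d$E0 > 0 & d$E0 <= 2.424e-5))
  # round 2 holds the point estimates fixed
  expect_true(all(d$mu_max == 1.38 & d$K_S == 0.840 & d$gamma == 0.0423))
  expect_true(all(d$D == 0.121 & d$n == 2))
  expect_identical(sample_parameters(sch2, 50, seed = 7),
                   sample_parameters(sch2, 50, seed = 7))
  expect_equal(nrow(sample_parameters(sch2, 0, seed = 1)), 0)
  # round 1 widens the bounds and jitters the point estimates
  d1 <- sample_parameters(sampling_scheme("round1"), 500, seed = 42)
  expect_gt(sd(d1$mu_max), 0)
  expect_true(any(d1$k_cat < 150))
  expect_true(all(d1$mu_max > 0))
})

test_that("the best-fit parameter set passes all three success criteria", {
  ev <- evaluate_success(best_fit, 3.00e-6)
  expect_true(ev$pass)
  expect_true(all(ev$flags))
  expect_gt(ev$metrics[["final_wt_biomass"]], 0.01)
  expect_lt(ev$metrics[["max_batch_od"]], 0.58)
  expect_gte(ev$metrics[["final_cheater_freq"]], 30)
})

test_that("pathological parameter sets fail the expected criterion", {
  # no burden: no selection gradient, frequency stuck at 10%
  ev_q0 <- evaluate_success(model_parameters(q = 0), 3.00e-6)
  expect_false(ev_q0$pass)
  expect_true("cheater_freq" %in% ev_q0$reasons)
  expect_equal(ev_q0$metrics[["final_cheater_freq"]], 10,
               tolerance = 1e-6)
  # dilution above achievable growth: cooperator washout
  ev_hiD <- evaluate_success(model_parameters(D = 1.0), 3.00e-6)
  expect_false(ev_hiD$pass)
  expect_true("wt_persists" %in% ev_hiD$reasons)
})

test_that("RMSE follows its definition and averages over replicates", {
  s <- observation_series(c(0, 24), c(0.3, 0.3), "od_coculture", "sim")
  o <- observation_series(c(0, 24), c(0.2, 0.4), "od_coculture", "1")
  expect_equal(rmse(s, o), 0.1)
  expect_equal(rmse(s, s), 0)
  # constant residual r gives |r|
  o2 <- observation_series(c(0, 24), c(0.25, 0.25), "od_coculture", "1")
  expect_equal(rmse(s, o2), 0.05)
  # replicate averaging is unweighted
  o3 <- rbind(o, observation_series(c(0, 24), c(0.3, 0.3),
                                    "od_coculture", "2"))
  expect_equal(rmse(s, o3), 0.05)
  expect_error(rmse(s, observation_series(900, 0.1, "od_coculture", "1")),
               "overlap")
})

test_that("score combination normalizes, weights, and ranks", {
  one <- data.frame(rmse_wt = 0.3, rmse_co = 0.2, rmse_freq = 5)
  expect_equal(combine_scores(one)$combined, 0)
  two <- data.frame(draw = 1:2, rmse_wt = c(0, 1), rmse_co = c(1, 0),
                    rmse_freq = c(1, 0))
  r <- combine_scores(two)
  expect_equal(r$combined, c(0.4, 0.8))
  expect_equal(r$draw, c(2, 1))  # second member dominates two columns
  # a member best in all three columns ranks first
  three <- data.frame(draw = 1:3, rmse_wt = c(3, 1, 2),
                      rmse_co = c(3, 1, 2), rmse_freq = c(3, 1, 2))
  expect_equal(combine_scores(three)$draw[1], 2)
  # permutation invariance
  perm <- three[c(2, 3, 1), ]
  expect_equal(combine_scores(perm)$combined,
               combine_scores(three)$combined)
})

test_that("candidate selection keeps the top decile and applies the
           end-of-batch filter", {
  ranked <- data.frame(combined = seq(0.1, 1, 0.1),
                       od_batch_end = c(0.45, rep(0.45, 8), 0.45),
                       freq_batch_end = c(35, rep(35, 8), 35))
  kept <- select_candidates(ranked, 0.10, od_bounds = c(0.4, 0.5))
  expect_equal(nrow(kept), 1)
  expect_equal(kept$combined, 0.1)
  # end-of-batch cheater frequency below 30% excludes a candidate
  ranked$freq_batch_end[1] <- 25
  expect_equal(nrow(select_candidates(ranked, 0.10, c(0.4, 0.5))), 0)
  # density outside the observed range excludes a candidate
  ranked$freq_batch_end[1] <- 35
  ranked$od_batch_end[1] <- 0.7
  expect_equal(nrow(select_candidates(ranked, 0.10, c(0.4, 0.5))), 0)
})

test_that("refinement is monotone and honours its step budget", {
  suite <- make_benchmark_suite(1001)
  toy <- suite$toy
  # zero budget returns the start unchanged
  r0 <- refine(best_fit, 3e-6, toy, max_iter = 0)
  expect_equal(r0$steps, 0)
  expect_equal(r0$params, best_fit)
  # perturbed start: the objective never increases and improves on the
  # perturbation
  pert <- best_fit
  pert$q <- pert$q * 1.2
  start_obj <- refine(pert, 3e-6, toy, max_iter = 0)$objective
  r <- refine(pert, 3e-6, toy, which = c("q", "QS_min"), max_iter = 4)
  expect_lte(r$objective, start_obj)
  expect_lte(r$steps, 4)
})

test_that("the fit pipeline is reproducible and reports its filters", {
  clean <- generate_dataset(synthetic_config(od_cv = 0, n_colonies = Inf,
                                             seed = 11))
  f1 <- fit_pipeline(clean, n_draws = 60, seed = 5,
                     refine_control = list(max_iter = 0))
  f2 <- fit_pipeline(clean, n_draws = 60, seed = 5,
                     refine_control = list(max_iter = 0))
  expect_equal(f1$results, f2$results)
  # a draw can violate several criteria at once
  expect_gte(sum(f1$failure_histogram), 60 - f1$n_success)
  expect_true(all(f1$failure_histogram <= 60))
  if (!is.null(f1$results)) {
    expect_true(all(diff(f1$results$combined) >= 0))
  }
  # excluded replicates do not enter the frequency data
  f3 <- fit_pipeline(clean, n_draws = 10, seed = 5,
                     exclude_replicates = c("R2"),
                     refine_control = list(max_iter = 0))
  expect_equal(f3$n_draws, 10)
})

test_that("an empty ensemble yields an empty report with a failure
           histogram", {
  clean <- generate_dataset(synthetic_config(od_cv = 0, n_colonies = Inf,
                                             n_replicates_wt = 1,
                                             n_replicates_co = 1,
                                             seed = 12))
  # force failure: draws restricted to a tiny no-burden corner
  sch <- sampling_scheme("round2", ranges = list(q = c(0.0425, 0.0426)))
  f <- fit_pipeline(clean, scheme = sch, n_draws = 8, seed = 2,
                    refine_control = list(max_iter = 0))
  expect_equal(f$n_success, 0)
  expect_null(f$best)
  expect_gte(sum(f$failure_histogram), 8)
  expect_equal(f$failure_histogram[["cheater_freq"]], 8)
})
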