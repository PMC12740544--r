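test_that("noise-free data with no inter-individual variability is recovered", {
  # identifiability of all six parameters needs samples spanning the fast
  # phase, so this fixture uses an 8-session schedule from 0.15 h out
  truth <- default_truth()
  nt <- c(TP1 = 0.15, TP2 = 0.7, TP3 = 3, TP4 = 10, TP5 = 24, TP6 = 48,
          TP7 = 96, TP8 = 160)
  cfg <- simulation_config(
    n_subjects = 3, nominal_times = nt, time_jitter_sd = rep(0.05, 8),
    truth = population_model(truth$theta, rep(0, 6), 1e-4),
    time_window = c(0.01, 235), seed = 5)
  g <- suppressWarnings(generate_cohort(cfg))
  f <- fit_population(
    g$cohort,
    init = population_model(truth$theta * 1.2, rep(1e-8, 6), 1e-3),
    control = fit_control(n_starts = 1, compute_cov = FALSE),
    fix_omega = rep(0, 6))
  expect_lt(max(abs(unname(f$model$theta) / unname(truth$theta) - 1)), 1e-3)
})

test_that("optimization never worsens the objective and reports diagnostics", {
  g <- small_cohort(n = 8, seed = 31)
  f <- suppressWarnings(fit_population(
    g$cohort,
    control = fit_control(n_starts = 3, seed = 2, compute_cov = TRUE)))
  expect_true(all(f$starts$ofv <= f$starts$ofv_init + 1e-8))
  expect_lte(f$ofv, min(f$starts$ofv) + 1e-6)
  expect_identical(f$n_obs, 40L)
  expect_identical(f$n_subjects, 8L)
  # covariance of the 13 estimates: symmetric, non-negative diagonal
  expect_identical(dim(f$est_cov), c(13L, 13L))
  expect_equal(f$est_cov, t(f$est_cov), tolerance = 1e-10)
  expect_true(all(diag(f$est_cov) >= 0))
  expect_identical(rownames(f$est_cov)[13], "sigma")
})

test_that("fitting refuses datasets below the degrees-of-freedom bound", {
  g <- small_cohort(n = 2, seed = 33)   # 10 observations < 13 + 1
  expect_error(fit_population(g$cohort), "degrees-of-freedom")
})

test_that("empirical-Bayes estimate shrinks to the prior and to the data", {
  model <- population_model(default_truth()$theta, rep(0.09, 6), 0.1)
  tt <- c(1.8, 18.7, 42.6, 66.3, 160.3)
  # observations exactly on the typical curve: with additive error the MAP
  # is exactly eta = 0; with proportional error the f-dependent variance
  # shifts the mode slightly below the curve, so only near-zero holds
  exact <- data.frame(subject_id = "z", time_h = tt,
                      activity_fraction = soef_eval(model$theta, tt),
                      tp_label = paste0("TP", 1:5))
  madd <- population_model(model$theta, model$omega, 0.002,
                           error_model = "additive")
  ind_add <- estimate_individual(madd, exact)
  expect_equal(ind_add$eta, rep(0, 6), tolerance = 1e-6)
  expect_equal(unclass(ind_add$params), model$theta, tolerance = 1e-6)
  ind <- estimate_individual(model, exact)
  expect_lt(max(abs(ind$eta)), 0.02)
  expect_equal(ind$param_cov, t(ind$param_cov), tolerance = 1e-12)
  expect_true(all(diag(ind$param_cov) >= 0))

  # MAP mode agrees with an independent optimizer on the oracle joint
  g <- small_cohort(n = 1, seed = 35)
  s <- as.data.frame(g$cohort)
  ind2 <- estimate_individual(model, s)
  oracle <- stats::optim(
    rep(0, 6),
    function(e) oracle_joint_neg2ll(model, s$time_h, s$activity_fraction, e),
    method = "BFGS", control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(ind2$eta, oracle$par, tolerance = 1e-3)

  # single-observation subset: the prior keeps the problem well-posed and
  # the mode matches the independent optimizer
  ind3 <- estimate_individual(model, s, subset = "TP3")
  s3 <- s[s$tp_label == "TP3", ]
  oracle3 <- stats::optim(
    rep(0, 6),
    function(e) oracle_joint_neg2ll(model, s3$time_h, s3$activity_fraction, e),
    method = "BFGS", control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(ind3$eta, oracle3$par, tolerance = 1e-3)
  expect_identical(ind3$n_obs, 1L)
  expect_identical(ind3$subset, "TP3")

  # vague prior: the estimate tracks the data rather than the prior
  vague <- population_model(model$theta, rep(25, 6), 0.1)
  indv <- estimate_individual(vague, s)
  resid_vague <- sum((s$activity_fraction -
                        soef_eval(indv$params, s$time_h))^2)
  resid_prior <- sum((s$activity_fraction -
                        soef_eval(ind2$params, s$time_h))^2)
  expect_lte(resid_vague, resid_prior + 1e-12)

  expect_error(estimate_individual(model, s, subset = character(0)), "empty")
  expect_error(estimate_individual(model, s, subset = "TP9"), "no samples")
})
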