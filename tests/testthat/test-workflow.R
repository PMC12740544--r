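# A homogeneous cohort (omega = 0, small noise) makes the reference and
# surrogate estimators nearly exact and cheap; it exercises the full chain.
test_that("homogeneous cohort: references hit truth, surrogates match them", {
  truth <- default_truth()
  cfg <- simulation_config(
    n_subjects = 6,
    truth = population_model(truth$theta, rep(0, 6), 1e-3), seed = 41)
  g <- suppressWarnings(generate_cohort(cfg))
  ref <- suppressWarnings(reference_tias(
    g$cohort, init = population_model(truth$theta * 1.2, rep(1e-3, 6), 0.01),
    control = fit_control(n_starts = 2, seed = 1, compute_cov = FALSE)))
  true_tia <- g$truth$true_tia_h[1]
  expect_true(all(abs(ref$tias$tia_h / true_tia - 1) < 0.005))
  expect_true(all(ref$tias$sd_h >= 0))
  expect_identical(unique(ref$tias$method), "ATP")
  expect_identical(unique(ref$tias$role), "reference")

  # identical subjects: the population mean/median parameter vector gives
  # back (almost) each subject's reference TIA
  for (mode in c("mean", "median")) {
    ntp <- ntp_tias(ref, mode)
    expect_identical(length(unique(ntp$tia_h)), 1L)
    rd <- (ntp$tia_h - ref$tias$tia_h) / ref$tias$tia_h
    expect_lt(max(abs(rd)), 0.01)
  }
})

test_that("NTP surrogate averages individual parameters componentwise", {
  # two subjects with parameters p and 3p: both the mean and the median of
  # the parameter vectors are 2p
  p <- unclass(soef_params(0.02, 0.01, 0.025, 0.005, 0.05, 2))
  fake <- structure(list(
    individuals = list(
      list(subject_id = "a",
           params = structure(p, class = "soef_params")),
      list(subject_id = "b",
           params = structure(3 * p, class = "soef_params"))),
    consts = physical_constants()), class = "reference_tias")
  for (mode in c("mean", "median")) {
    ntp <- ntp_tias(fake, mode)
    expect_equal(unique(ntp$tia_h), soef_tia(2 * p), tolerance = 1e-12)
  }
  expect_identical(ntp_tias(fake, "mean")$method[1], "NTPme")
  expect_identical(ntp_tias(fake, "median")$method[1], "NTPmd")
})

test_that("jackknife estimation never sees the left-out subject's data", {
  g <- small_cohort(n = 8, seed = 43)
  ctl <- fit_control(n_starts = 1, loo_n_starts = 1, compute_cov = FALSE)
  loo <- loo_fits(g$cohort, control = ctl)
  expect_identical(length(loo), 8L)
  sub3 <- subset_label(3)
  est <- ftp_tias_jackknife(g$cohort, sub3, loo, control = ctl)
  expect_identical(nrow(est), 8L)
  expect_true(all(est$tia_h > 0))
  expect_true(all(est$sd_h >= 0))
  expect_equal(est$cv, est$sd_h / est$tia_h, tolerance = 1e-12)

  # perturb every observation of subject S001 EXCEPT its TP3 sample, then
  # redo the whole pipeline: S001's estimate must be bit-identical
  pert <- as.data.frame(g$cohort)
  rows <- pert$subject_id == "S001" & pert$tp_label != "TP3"
  pert$activity_fraction[rows] <- pert$activity_fraction[rows] * 1.5
  pert <- cohort_dataset(pert)
  loo_p <- loo_fits(pert, control = ctl)
  est_p <- ftp_tias_jackknife(pert, sub3, loo_p, control = ctl)
  expect_equal(est_p$tia_h[est_p$subject_id == "S001"],
               est$tia_h[est$subject_id == "S001"], tolerance = 1e-10)
  expect_equal(est_p$sd_h[est_p$subject_id == "S001"],
               est$sd_h[est$subject_id == "S001"], tolerance = 1e-10)

  # ATP is not a valid few-time-point subset
  expect_error(ftp_tias_jackknife(g$cohort, subset_label(1:5), loo),
               "proper subset")
})

test_that("the orchestrated study assembles consistent tables", {
  g <- small_cohort(n = 8, seed = 45)
  st <- suppressWarnings(run_ftp_study(
    g$cohort, control = fit_control(n_starts = 2, seed = 4,
                                    compute_cov = FALSE),
    subsets = list("TP3", c("TP2", "TP5"))))
  expect_setequal(st$accuracy$method, c("TP3", "TP25", "NTPme", "NTPmd"))
  expect_true(all(st$tias$tia_h > 0))
  expect_true(all(st$tias$sd_h >= 0))
  expect_identical(sum(st$tias$role == "reference"), 8L)
  expect_identical(st$cv$method[1], "ATP")
  b <- st$best
  expect_identical(b$method, c("TP3", "TP25"))
  expect_true(all(c("rmse", "mape", "rd10", "rd20", "slope",
                    "p_slope") %in% names(st$accuracy)))
  # report writer consumes the study object directly
  f <- tempfile(fileext = ".csv")
  files <- write_report(st, f)
  expect_length(files, 2L)
  expect_true(all(file.exists(files)))
  unlink(files)
})
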