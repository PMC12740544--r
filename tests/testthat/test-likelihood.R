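test_that("joint -2LL matches a density-based oracle, with gradient", {
  set.seed(501)
  for (em in c("proportional", "additive")) {
    model <- population_model(default_truth()$theta,
                              c(0.09, 0.04, 0.09, 0.16, 0.09, 0.25),
                              if (em == "proportional") 0.1 else 0.002,
                              error_model = em)
    tt <- c(1.8, 18.7, 42.6, 66.3, 160.3)
    f <- soef_eval(default_truth()$theta, tt)
    for (i in 1:5) {
      eta <- stats::rnorm(6, 0, 0.3)
      y <- pmax(f * (1 + stats::rnorm(5, 0, 0.1)), 0)
      subj <- data.frame(subject_id = "s", time_h = tt, activity_fraction = y)
      got <- joint_neg2ll(model, subj, eta)
      expect_equal(as.numeric(got), oracle_joint_neg2ll(model, tt, y, eta),
                   tolerance = 1e-10)
      # analytic gradient vs central differences of the oracle
      g <- attr(got, "gradient")
      for (j in 1:6) {
        h <- 1e-6
        ep <- eta; em_ <- eta
        ep[j] <- ep[j] + h; em_[j] <- em_[j] - h
        fd <- (oracle_joint_neg2ll(model, tt, y, ep) -
                 oracle_joint_neg2ll(model, tt, y, em_)) / (2 * h)
        expect_equal(g[j], fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("a +1 sigma perturbation adds exactly one standardized unit", {
  model <- population_model(default_truth()$theta, rep(1, 6), 0.1)
  tt <- 42.6
  f <- soef_eval(default_truth()$theta, tt)
  base <- data.frame(subject_id = "s", time_h = tt, activity_fraction = f)
  pert <- base
  pert$activity_fraction <- f + 0.1 * f
  d <- as.numeric(joint_neg2ll(model, pert, rep(0, 6))) -
    as.numeric(joint_neg2ll(model, base, rep(0, 6)))
  expect_equal(d, 1, tolerance = 1e-10)
})

test_that("Laplace approximation is exact for a model linear in eta", {
  # y_i ~ N(theta + eta, sigma^2), eta ~ N(0, omega^2)
  direct_marginal <- function(y, theta, omega, sigma) {
    # y ~ MVN(theta * 1, sigma^2 I + omega^2 J): exact closed form
    n <- length(y)
    r <- y - theta
    quad <- (sum(r^2) - omega^2 / (sigma^2 + n * omega^2) * sum(r)^2) /
      sigma^2
    n * log(2 * pi) + (n - 1) * log(sigma^2) +
      log(sigma^2 + n * omega^2) + quad
  }
  set.seed(502)
  for (i in 1:5) {
    theta <- stats::runif(1, -2, 2)
    omega <- stats::runif(1, 0.3, 2)
    sigma <- stats::runif(1, 0.2, 1)
    y <- stats::rnorm(4, theta, sqrt(omega^2 + sigma^2))
    joint <- function(eta)
      -2 * (sum(stats::dnorm(y, theta + eta[1], sigma, log = TRUE)) +
              stats::dnorm(eta[1], 0, omega, log = TRUE))
    lap <- laplace_neg2ll(joint, 0)
    expect_equal(lap$value, direct_marginal(y, theta, omega, sigma),
                 tolerance = 1e-8)
  }
})

test_that("compiled per-subject marginal agrees with the generic machinery", {
  model <- population_model(default_truth()$theta, rep(0.09, 6), 0.1)
  g <- small_cohort(n = 3, seed = 91)
  subs <- split(as.data.frame(g$cohort), g$cohort$subject_id)
  for (s in subs) {
    fast <- laplace_subject_neg2ll(model, s)
    joint <- function(eta) as.numeric(joint_neg2ll(model, s, eta))
    slow <- laplace_neg2ll(joint, fast$eta)
    expect_equal(fast$value, slow$value, tolerance = 1e-4)
    expect_equal(fast$eta, slow$eta, tolerance = 1e-4)
  }
})

test_that("one-dimensional eta: Laplace within 1% of grid integration", {
  model <- population_model(default_truth()$theta,
                            c(0.25, 0, 0, 0, 0, 0), 0.1)
  g <- small_cohort(n = 1, seed = 93)
  s <- as.data.frame(g$cohort)
  lap <- laplace_subject_neg2ll(model, s)
  grid <- seq(-3, 3, length.out = 4001)
  vals <- vapply(grid, function(e)
    as.numeric(joint_neg2ll(model, s, c(e, 0, 0, 0, 0, 0))), numeric(1))
  h <- diff(grid[1:2])
  integral <- sum(exp(-(vals - min(vals)) / 2)) * h * exp(-min(vals) / 2)
  expect_equal(lap$value, -2 * log(integral), tolerance = 0.01)
})

test_that("degenerate prior: marginal collapses to the joint at eta = 0", {
  base <- default_truth()
  tiny <- population_model(base$theta, rep(1e-12, 6), 0.1)
  point <- population_model(base$theta, rep(0, 6), 0.1)
  g <- small_cohort(n = 2, seed = 95)
  for (s in split(as.data.frame(g$cohort), g$cohort$subject_id)) {
    m_tiny <- laplace_subject_neg2ll(tiny, s)$value
    j0 <- as.numeric(joint_neg2ll(point, s, rep(0, 6)))
    expect_equal(m_tiny, j0, tolerance = 1e-6)
  }
})

test_that("marginal -2LL is additive over subjects", {
  model <- population_model(default_truth()$theta, rep(0.09, 6), 0.1)
  g <- small_cohort(n = 5, seed = 97)
  total <- marginal_neg2ll(model, g$cohort)
  per <- attr(total, "per_subject")
  # equals the brute-force sum of per-subject contributions
  singles <- vapply(split(as.data.frame(g$cohort), g$cohort$subject_id),
                    function(s) laplace_subject_neg2ll(model, s)$value,
                    numeric(1))
  expect_equal(as.numeric(total), sum(singles), tolerance = 1e-10)
  expect_equal(sort(unname(per)), sort(unname(singles)), tolerance = 1e-10)

  # duplicating a subject doubles its contribution
  one <- as.data.frame(g$cohort)[g$cohort$subject_id == "S001", ]
  two <- one
  two$subject_id <- "S001b"
  both <- cohort_dataset(rbind(one, two))
  expect_equal(as.numeric(marginal_neg2ll(model, both)),
               2 * laplace_subject_neg2ll(model, one)$value,
               tolerance = 1e-10)
})

test_that("eta is pinned to zero where omega is zero", {
  model <- population_model(default_truth()$theta,
                            c(0.09, 0, 0.09, 0, 0.09, 0), 0.1)
  g <- small_cohort(n = 1, seed = 99)
  s <- as.data.frame(g$cohort)
  expect_error(joint_neg2ll(model, s, rep(0.1, 6)), "point-mass")
  lap <- laplace_subject_neg2ll(model, s)
  expect_identical(lap$eta[c(2, 4, 6)], rep(0, 3))
})
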