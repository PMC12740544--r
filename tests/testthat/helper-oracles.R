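# Independent oracles used across the suite. All are written from the model
# definitions directly (dnorm, quadrature, normal equations), not through the
# package's computational paths.

# term-by-term curve evaluation (independent of the compiled path)
oracle_soef <- function(p, t, consts = physical_constants()) {
  lp <- consts$lambda_phys
  lbc <- consts$lambda_bc
  p <- unclass(p)
  p[["A1"]] * exp(-(p[["lambda1"]] + lp) * t) +
    p[["A2"]] * exp(-(p[["lambda2"]] + lp) * t) -
    p[["A3"]] * exp(-(p[["lambda3"]] + lp) * t) -
    (p[["A1"]] + p[["A2"]] - p[["A3"]]) * exp(-(lbc + lp) * t)
}

# adaptive-quadrature TIA
oracle_tia_quad <- function(p, consts = physical_constants(),
                            rel.tol = 1e-10) {
  stats::integrate(function(t) oracle_soef(p, t, consts), 0, Inf,
                   rel.tol = rel.tol, abs.tol = 0)$value
}

# random valid parameter draws spanning the plausible kinetic range
random_params <- function() {
  soef_params(A1 = stats::runif(1, 0.005, 0.1),
              A2 = stats::runif(1, 0.002, 0.05),
              A3 = stats::runif(1, 0.002, 0.05),
              lambda1 = stats::runif(1, 0.001, 0.02),
              lambda2 = stats::runif(1, 0.02, 0.3),
              lambda3 = stats::runif(1, 0.5, 5))
}

# joint -2LL written directly from Gaussian densities
oracle_joint_neg2ll <- function(model, t, y, eta,
                                consts = physical_constants(),
                                floor = 1e-9) {
  p <- unname(model$theta) * exp(eta)
  f <- oracle_soef(stats::setNames(p, names(model$theta)), t, consts)
  fv <- pmax(f, floor)
  v <- switch(model$error_model,
              proportional = (model$sigma[1] * fv)^2,
              additive = rep(model$sigma[1]^2, length(f)),
              combined = model$sigma[2]^2 + (model$sigma[1] * fv)^2)
  ll <- sum(stats::dnorm(y, mean = f, sd = sqrt(v), log = TRUE))
  free <- model$omega > 0
  if (any(free))
    ll <- ll + sum(stats::dnorm(eta[free], 0, sqrt(model$omega[free]),
                                log = TRUE))
  -2 * ll
}

# small deterministic cohort for fitting tests
small_cohort <- function(n = 8, seed = 77, sigma = 0.1) {
  truth <- population_model(default_truth()$theta, rep(0.09, 6), sigma)
  cfg <- simulation_config(n_subjects = n, truth = truth, seed = seed)
  suppressWarnings(generate_cohort(cfg))
}

# canonicalize the two positive phases of a theta vector by rate ordering
# (the curve is invariant under exchanging (A1, lambda1) and (A2, lambda2))
canonicalize_phases <- function(theta) {
  theta <- unname(theta)
  if (theta[4] > theta[5])
    theta <- theta[c(2, 1, 3, 5, 4, 6)]
  theta
}
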