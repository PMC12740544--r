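#' Control settings for population fitting
#'
#' @param n_starts Number of multi-start initializations; the first start is
#'   the supplied centers, the rest are log-uniform draws around them.
#' @param theta_spread,omega_spread,sigma_spread Half-width of the
#'   log-uniform start draws, in decades.
#' @param seed Seed for the start draws (NULL leaves the RNG stream alone).
#' @param grad_tol,max_inner Inner (eta) Newton tolerance and iteration cap.
#' @param outer_iter,outer_eval,outer_rel_tol [stats::nlminb()] budget and
#'   relative tolerance for the outer minimization.
#' @param loo_n_starts Multi-start count for leave-one-out training fits
#'   (see [loo_fits()]); kept separate because N training fits are run.
#' @param curvature Curvature of the per-subject log-determinant correction:
#'   `"observed"` (strict Laplacian) or `"expected"` (Fisher information).
#' @param compute_cov Compute the covariance of the population estimates by
#'   a central finite-difference Hessian at the optimum.
#' @param cov_step Finite-difference step on the log scale.
#' @param floor Residual-variance floor for `f(t)` (see [joint_neg2ll()]).
#' @return List of class `fit_control`.
#' @export
fit_control <- function(n_starts = 10L, theta_spread = 1, omega_spread = 0.5,
                        sigma_spread = 0.5, seed = NULL, loo_n_starts = 3L,
                        grad_tol = 1e-8, max_inner = 100L,
                        outer_iter = 500L, outer_eval = 3000L,
                        outer_rel_tol = 1e-12,
                        curvature = c("observed", "expected"),
                        compute_cov = TRUE, cov_step = 1e-4,
                        floor = FMIN_FLOOR) {
  curvature <- match.arg(curvature)
  structure(list(n_starts = as.integer(n_starts), theta_spread = theta_spread,
                 omega_spread = omega_spread, sigma_spread = sigma_spread,
                 seed = seed, loo_n_starts = as.integer(loo_n_starts),
                 grad_tol = grad_tol,
                 max_inner = as.integer(max_inner),
                 outer_iter = as.integer(outer_iter),
                 outer_eval = as.integer(outer_eval),
                 outer_rel_tol = outer_rel_tol, curvature = curvature,
                 compute_cov = compute_cov,
                 cov_step = cov_step, floor = floor),
            class = "fit_control")
}

#' Default starting centers for population fitting
#'
#' Generic, deliberately rough centers on the scale of renal kinetics of a
#' 177Lu-labelled ligand (uptake fractions in the percent range, slow and
#' fast clearance phases); the multi-start machinery explores around them.
#'
#' @param error_model Residual model tag, passed to [population_model()].
#' @return A [population_model()] usable as `init` in [fit_population()].
#' @export
default_init <- function(error_model = "proportional") {
  sigma <- if (error_model == "combined") c(0.2, 0.001) else 0.2
  population_model(theta = c(A1 = 0.03, A2 = 0.02, A3 = 0.03,
                             lambda1 = 0.01, lambda2 = 0.1, lambda3 = 1),
                   omega = rep(0.1, 6), sigma = sigma,
                   error_model = error_model)
}

#' @keywords internal
pack_x <- function(model) {
  c(log(unname(model$theta)), log(pmax(unname(model$omega), 1e-8)),
    log(model$sigma))
}

#' @keywords internal
unpack_model <- function(x, error_model) {
  n_sig <- if (error_model == "combined") 2L else 1L
  population_model(theta = exp(x[1:6]), omega = exp(x[7:12]),
                   sigma = exp(x[12 + seq_len(n_sig)]),
                   error_model = error_model)
}

#' @keywords internal
x_names <- function(error_model) {
  nm <- c(soef_param_names(), paste0("omega_", soef_param_names()))
  if (error_model == "combined") c(nm, "sigma_prop", "sigma_add")
  else c(nm, "sigma")
}

#' Fit the population model to a cohort by Laplacian marginal likelihood
#'
#' Minimizes the cohort marginal -2 log-likelihood ([marginal_neg2ll()])
#' over the log-transformed population parameters (log theta, log omega,
#' log sigma — the transform enforces positivity) with [stats::nlminb()],
#' restarting from `n_starts` log-uniform perturbations of the supplied
#' centers and keeping the best objective value (ties: lowest start index).
#' Conditional modes are always searched from `eta = 0` so that the
#' objective is a deterministic function of the population parameters.
#'
#' Fitting refuses datasets with fewer observations than estimated
#' parameters plus one (the degrees-of-freedom requirement `K + 1 <= N`).
#'
#' @param dataset An `ftp_cohort` data frame.
#' @param init A [population_model()] of starting centers.
#' @param control A [fit_control()].
#' @param consts [physical_constants()].
#' @param fix_omega Optional length-6 vector: hold the random-effect
#'   variances fixed at these values (entries of 0 switch the random effect
#'   off entirely) and estimate only `theta` and `sigma`. Lowers the
#'   estimated-parameter count accordingly.
#' @return Object of class `population_fit`: `model` (estimates), `ofv`,
#'   `est_cov` (covariance of the 13 estimates on the natural scale, from
#'   the inverse finite-difference Hessian of half the objective),
#'   `converged`, `n_obs`, `starts` (per-start diagnostics), `eta_hat`
#'   (6 x N conditional modes at the optimum).
#' @export
fit_population <- function(dataset, init = default_init(),
                           control = fit_control(),
                           consts = physical_constants(), fix_omega = NULL) {
  stopifnot(inherits(init, "population_model"), inherits(control, "fit_control"))
  dataset <- if (inherits(dataset, "ftp_cohort")) dataset else
    cohort_dataset(dataset)
  subs <- split_subjects(dataset)
  n_obs <- nrow(dataset)
  omega_fixed <- !is.null(fix_omega)
  if (omega_fixed) {
    if (length(fix_omega) != 6L || any(!is.finite(fix_omega)) ||
        any(fix_omega < 0))
      stop("'fix_omega' must be six finite non-negative variances",
           call. = FALSE)
    fix_omega <- as.numeric(fix_omega)
  }
  k <- n_parameters(init) - if (omega_fixed) 6L else 0L
  if (n_obs < k + 1L)
    stop("degrees-of-freedom requirement violated: ", n_obs,
         " observations for ", k, " estimated parameters (need >= ", k + 1L,
         ")", call. = FALSE)

  ev_names <- init$error_model
  t_list <- lapply(subs, `[[`, "time_h")
  y_list <- lapply(subs, `[[`, "activity_fraction")
  n_sub <- length(subs)
  lp <- consts$lambda_phys; lbc <- consts$lambda_bc

  # conditional modes are always searched from eta = 0 so that the objective
  # is a deterministic function of x (a warm-started inner search can land in
  # a different posterior mode and make the outer objective inconsistent)
  last <- new.env(parent = emptyenv())
  last$eta <- matrix(0, 6, n_sub)
  n_sig <- length(init$sigma)
  expand_x <- function(x) {
    if (!omega_fixed) return(x)
    c(x[1:6], log(pmax(fix_omega, 1e-300)), x[6 + seq_len(n_sig)])
  }
  objective <- function(x) {
    m <- tryCatch({
      xx <- expand_x(x)
      m <- unpack_model(xx, ev_names)
      if (omega_fixed) m$omega[] <- fix_omega  # allow exact zeros
      m
    }, error = function(e) NULL)
    if (is.null(m)) return(1e10)
    ev <- error_variances(m)
    r <- cpp_marginal_neg2ll(unname(m$theta), unname(m$omega),
                             ev[["s2a"]], ev[["s2p"]], control$floor,
                             t_list, y_list, matrix(0, 6, n_sub), lp, lbc,
                             control$grad_tol, control$max_inner,
                             if (control$curvature == "expected") 1L else 0L)
    if (!is.finite(r$value)) return(1e10)
    last$eta <- r$eta
    r$value
  }

  # prefactors are fractions of injected activity, so they cannot exceed 1;
  # rates are bounded loosely
  lower <- c(rep(log(1e-8), 6),
             if (!omega_fixed) rep(log(1e-8), 6), rep(log(1e-6), n_sig))
  upper <- c(rep(log(1), 3), rep(log(1e3), 3),
             if (!omega_fixed) rep(log(25), 6), rep(log(5), n_sig))
  x0_full <- pack_x(init)
  x0 <- if (omega_fixed) x0_full[-(7:12)] else x0_full
  x0 <- pmin(pmax(x0, lower), upper)

  if (!is.null(control$seed)) set.seed(control$seed)
  starts <- vector("list", control$n_starts)
  starts[[1L]] <- x0
  if (control$n_starts > 1L) {
    spread <- c(rep(control$theta_spread, 6),
                if (!omega_fixed) rep(control$omega_spread, 6),
                rep(control$sigma_spread, n_sig))
    for (s in 2:control$n_starts)
      starts[[s]] <- pmin(pmax(
        x0 + log(10) * stats::runif(length(x0), -spread, spread),
        lower), upper)
  }

  results <- vector("list", control$n_starts)
  for (s in seq_len(control$n_starts)) {
    ofv0 <- objective(starts[[s]])
    fit <- tryCatch(
      stats::nlminb(starts[[s]], objective, lower = lower, upper = upper,
                    control = list(iter.max = control$outer_iter,
                                   eval.max = control$outer_eval,
                                   rel.tol = control$outer_rel_tol)),
      error = function(e) NULL)
    results[[s]] <- if (is.null(fit)) {
      list(ofv = Inf, ofv0 = ofv0, par = starts[[s]], conv = FALSE,
           message = "optimizer error")
    } else {
      # PORT reports small kink-induced gradient-test failures as "false
      # convergence" even when the iterates have settled; treat any
      # *-convergence message except singular convergence as converged
      ok <- fit$convergence == 0L ||
        grepl("convergence", fit$message) &&
        !grepl("singular|iteration|evaluation", fit$message)
      list(ofv = fit$objective, ofv0 = ofv0, par = fit$par,
           conv = ok, message = fit$message)
    }
  }
  ofvs <- vapply(results, `[[`, 0, "ofv")
  if (all(!is.finite(ofvs)))
    stop("population fit failed for every start", call. = FALSE)
  best <- which.min(ofvs)   # ties resolve to the lowest index
  bx <- results[[best]]$par
  # polish the winning start without box constraints: PORT's bounded branch
  # stalls on the long flat valleys of this likelihood, while the unbounded
  # branch tracks them; the objective itself guards degenerate regions and
  # the result is clamped back into the box
  ofv_best <- ofvs[best]
  for (polish in 1:3) {
    pf <- tryCatch(
      stats::nlminb(bx, objective,
                    control = list(iter.max = control$outer_iter,
                                   eval.max = control$outer_eval,
                                   rel.tol = control$outer_rel_tol)),
      error = function(e) NULL)
    if (is.null(pf)) break
    px <- pmin(pmax(pf$par, lower), upper)
    pofv <- if (all(px == pf$par)) pf$objective else objective(px)
    if (pofv > ofv_best - 1e-7) break
    ofv_best <- pofv
    bx <- px
  }
  model <- unpack_model(expand_x(bx), ev_names)
  if (omega_fixed) model$omega[] <- fix_omega

  # recompute at the optimum to refresh the conditional modes
  ofv <- objective(bx)
  eta_hat <- last$eta
  colnames(eta_hat) <- vapply(subs, `[[`, "", "subject_id")

  est_cov <- NULL
  cov_ok <- NA
  if (isTRUE(control$compute_cov)) {
    H <- fd_hessian_r(function(x) objective(x) / 2, bx, control$cov_step)
    est_nat <- exp(bx)
    cov_x <- tryCatch(solve(H), error = function(e) NULL)
    cov_ok <- !is.null(cov_x) && all(diag(cov_x) >= 0)
    if (!cov_ok) {  # clipped-eigenvalue pseudo-inverse fallback
      ei <- eigen(H, symmetric = TRUE)
      vals <- pmax(ei$values, 1e-10 * max(abs(ei$values)))
      cov_x <- ei$vectors %*% diag(1 / vals) %*% t(ei$vectors)
    }
    est_cov <- diag(est_nat) %*% cov_x %*% t(diag(est_nat))
    est_cov <- (est_cov + t(est_cov)) / 2
    nm <- if (omega_fixed) x_names(ev_names)[-(7:12)] else x_names(ev_names)
    dimnames(est_cov) <- list(nm, nm)
  }

  structure(list(
    model = model, ofv = ofv, est_cov = est_cov, cov_ok = cov_ok,
    converged = results[[best]]$conv, n_obs = n_obs, n_subjects = n_sub,
    eta_hat = eta_hat,
    starts = data.frame(start = seq_along(results),
                        ofv_init = vapply(results, `[[`, 0, "ofv0"),
                        ofv = ofvs,
                        converged = vapply(results, `[[`, TRUE, "conv")),
    best_start = best, control = control, consts = consts,
    estimates = stats::setNames(
      exp(bx),
      if (omega_fixed) x_names(ev_names)[-(7:12)] else x_names(ev_names))
  ), class = "population_fit")
}

# central finite-difference Hessian of a scalar function
#' @keywords internal
fd_hessian_r <- function(fn, x, h = 1e-4) {
  k <- length(x)
  H <- matrix(0, k, k)
  f0 <- fn(x)
  for (i in seq_len(k)) {
    ei <- rep(0, k); ei[i] <- h
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h^2
    if (i < k) for (j in (i + 1):k) {
      ej <- rep(0, k); ej[j] <- h
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) +
           fn(x - ei - ej)) / (4 * h^2)
    }
  }
  H
}

#' @export
print.population_fit <- function(x, ...) {
  cat("Population fit:", x$n_subjects, "subjects,", x$n_obs, "observations\n")
  cat("  OFV:", format(x$ofv, digits = 10),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(x$model)
  invisible(x)
}

#' Empirical-Bayes individual estimate from a session subset
#'
#' Maximum-a-posteriori random effects for one subject given a fixed
#' population model, using only the observations whose session labels fall
#' in `subset`. The population prior makes the problem well-posed even for a
#' single observation. The individual parameter covariance is
#' `J H^{-1} J'` with `H` the expected-information (Fisher) curvature of
#' the negative log posterior in `eta` at the mode — positive definite by
#' construction, unlike the observed Hessian, whose data part can lose
#' definiteness at a barely-curved mode — and `J = diag(params)` the
#' Jacobian of the log-normal map.
#'
#' @param pop A [population_fit()] or [population_model()].
#' @param subject Data frame or per-subject record (needs `tp_label` when
#'   `subset` is not NULL).
#' @param subset Character vector of session labels (e.g. `c("TP2","TP5")`),
#'   a `subset_label`, or NULL for all samples.
#' @param consts [physical_constants()].
#' @param control A [fit_control()] (inner tolerances and floor are used).
#' @return Object of class `individual_estimate`: `subject_id`, `eta`,
#'   `params` ([soef_params()]), `param_cov` (6x6), `subset`, `n_obs`,
#'   `converged`.
#' @export
estimate_individual <- function(pop, subject, subset = NULL,
                                consts = physical_constants(),
                                control = fit_control()) {
  model <- if (inherits(pop, "population_fit")) pop$model else pop
  stopifnot(inherits(model, "population_model"))
  s <- as_subject(subject)
  keep <- seq_along(s$time_h)
  subset_name <- "ATP"
  if (!is.null(subset)) {
    labels <- if (inherits(subset, "subset_label")) subset$labels
              else as.character(subset)
    if (length(labels) == 0L) stop("empty session subset", call. = FALSE)
    if (is.null(s$tp_label))
      stop("subject has no tp_label; cannot select a session subset",
           call. = FALSE)
    keep <- which(s$tp_label %in% labels)
    if (length(keep) == 0L)
      stop("subject '", s$subject_id, "' has no samples in subset {",
           paste(labels, collapse = ","), "}", call. = FALSE)
    subset_name <- if (inherits(subset, "subset_label")) subset$name
                   else paste(labels, collapse = "+")
  }
  ev <- error_variances(model)
  r <- cpp_inner_laplace(unname(model$theta), unname(model$omega),
                         ev[["s2a"]], ev[["s2p"]], control$floor,
                         s$time_h[keep], s$activity_fraction[keep],
                         rep(0, 6), consts$lambda_phys, consts$lambda_bc,
                         control$grad_tol, control$max_inner)
  eta <- as.numeric(r$eta)
  params <- individual_params(model$theta, eta)
  free <- which(unname(model$omega) > 0)
  cov_eta <- matrix(0, 6, 6)
  if (length(free)) {
    Ihalf <- cpp_expected_info_half(unname(model$theta), unname(model$omega),
                                    ev[["s2a"]], ev[["s2p"]], control$floor,
                                    s$time_h[keep], s$activity_fraction[keep],
                                    eta, consts$lambda_phys, consts$lambda_bc)
    Ihalf <- Ihalf[free, free, drop = FALSE]
    # eigendecomposition inverse with clipping against numerical rank loss
    ei <- eigen(Ihalf, symmetric = TRUE)
    vals <- pmax(ei$values, 1e-12 * max(abs(ei$values), 1e-300))
    cv <- ei$vectors %*% diag(1 / vals, length(vals)) %*% t(ei$vectors)
    cov_eta[free, free] <- (cv + t(cv)) / 2
  }
  D <- diag(unclass(params))
  param_cov <- D %*% cov_eta %*% D
  param_cov <- (param_cov + t(param_cov)) / 2
  dimnames(param_cov) <- list(soef_param_names(), soef_param_names())
  structure(list(subject_id = s$subject_id, eta = eta, params = params,
                 param_cov = param_cov, subset = subset_name,
                 n_obs = length(keep), converged = r$converged),
            class = "individual_estimate")
}
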