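#' @keywords internal
as_subject <- function(subject) {
  if (is.data.frame(subject)) {
    sid <- if (!is.null(subject$subject_id)) subject$subject_id[1L] else "subject"
    list(subject_id = as.character(sid), time_h = subject$time_h,
         activity_fraction = subject$activity_fraction,
         tp_label = subject$tp_label)
  } else if (is.list(subject) &&
             all(c("time_h", "activity_fraction") %in% names(subject))) {
    subject
  } else stop("'subject' must be a data frame or per-subject record",
              call. = FALSE)
}

# model floor for f(t) inside the proportional residual variance
FMIN_FLOOR <- 1e-9

#' Joint -2 log-likelihood of one subject's data and random effects
#'
#' `-2 [ log p(y | eta) + log p(eta | omega) ]` for the kinetics model:
#' observations are Gaussian around `f(t)` with the model's residual variance
#' (proportional variance uses `max(f, floor)` to stay positive near the
#' curve's zero crossing), and `eta ~ N(0, diag(omega))`. Components with
#' `omega_j = 0` are point masses at zero and contribute no prior term.
#'
#' @param model A [population_model()].
#' @param subject Data frame or per-subject record with `time_h` and
#'   `activity_fraction`.
#' @param eta Length-6 random-effect vector.
#' @param consts [physical_constants()].
#' @param floor Lower bound for `f(t)` inside the residual variance.
#' @return Scalar -2LL; attribute `"gradient"` holds the analytic gradient
#'   in `eta`.
#' @export
joint_neg2ll <- function(model, subject, eta, consts = physical_constants(),
                         floor = FMIN_FLOOR) {
  stopifnot(inherits(model, "population_model"))
  s <- as_subject(subject)
  if (length(s$time_h) < 1L) stop("subject has no samples", call. = FALSE)
  if (length(eta) != 6L || any(!is.finite(eta)))
    stop("'eta' must be six finite numbers", call. = FALSE)
  if (any(model$omega == 0 & abs(eta) > 0))
    stop("eta must be 0 where omega is 0 (point-mass prior)", call. = FALSE)
  ev <- error_variances(model)
  r <- cpp_joint_neg2ll(unname(model$theta), unname(model$omega),
                        ev[["s2a"]], ev[["s2p"]], floor,
                        s$time_h, s$activity_fraction, as.numeric(eta),
                        consts$lambda_phys, consts$lambda_bc, TRUE)
  structure(r$value, gradient = as.numeric(r$grad))
}

#' Laplace-approximate marginal -2LL contribution of one subject
#'
#' Minimizes [joint_neg2ll()] over `eta` (damped Newton from `eta_init`) and
#' applies the Laplace correction
#' `joint(eta_hat) + log det( H/2 / (2 pi) )`, where `H` is the Hessian of
#' the joint -2LL at the mode (so `H/2` is the curvature of the negative
#' log posterior). Components with `omega_j = 0` are held at zero and do not
#' enter the determinant.
#'
#' @inheritParams joint_neg2ll
#' @param eta_init Starting value for the inner optimization.
#' @param grad_tol Inner gradient tolerance.
#' @param max_iter Inner iteration cap.
#' @param curvature Curvature used in the log-determinant correction:
#'   `"observed"` (the strict Laplacian choice, finite-difference Hessian of
#'   the joint -2LL) or `"expected"` (Fisher information; smooth and
#'   positive definite everywhere).
#' @return List with `value` (marginal -2LL contribution), `joint` (joint
#'   -2LL at the mode), `eta` (the conditional mode), `hessian` (6x6 Hessian
#'   of the joint -2LL, zero rows for fixed components), `converged`.
#' @export
laplace_subject_neg2ll <- function(model, subject,
                                   eta_init = rep(0, 6),
                                   consts = physical_constants(),
                                   floor = FMIN_FLOOR,
                                   grad_tol = 1e-8, max_iter = 100L,
                                   curvature = c("observed", "expected")) {
  stopifnot(inherits(model, "population_model"))
  curvature <- match.arg(curvature)
  s <- as_subject(subject)
  ev <- error_variances(model)
  r <- cpp_inner_laplace(unname(model$theta), unname(model$omega),
                         ev[["s2a"]], ev[["s2p"]], floor,
                         s$time_h, s$activity_fraction, as.numeric(eta_init),
                         consts$lambda_phys, consts$lambda_bc,
                         grad_tol, as.integer(max_iter),
                         if (curvature == "expected") 1L else 0L)
  if (!r$converged)
    warning("inner eta optimization did not meet the gradient tolerance ",
            "for subject '", s$subject_id, "'; using best point found",
            call. = FALSE)
  r$eta <- as.numeric(r$eta)
  r
}

#' Marginal -2 log-likelihood of a cohort
#'
#' Sum of [laplace_subject_neg2ll()] contributions over the cohort's
#' subjects (the population objective function value, OFV).
#'
#' @param model A [population_model()].
#' @param dataset An `ftp_cohort` data frame.
#' @inheritParams laplace_subject_neg2ll
#' @param curvature Correction curvature, `"observed"` or `"expected"`.
#' @return Scalar OFV with attribute `"per_subject"` (named contributions).
#' @export
marginal_neg2ll <- function(model, dataset, consts = physical_constants(),
                            floor = FMIN_FLOOR, grad_tol = 1e-8,
                            max_iter = 100L,
                            curvature = c("observed", "expected")) {
  stopifnot(inherits(model, "population_model"))
  curvature <- match.arg(curvature)
  subs <- split_subjects(dataset)
  if (length(subs) == 0L) stop("empty dataset", call. = FALSE)
  ev <- error_variances(model)
  r <- cpp_marginal_neg2ll(unname(model$theta), unname(model$omega),
                           ev[["s2a"]], ev[["s2p"]], floor,
                           lapply(subs, `[[`, "time_h"),
                           lapply(subs, `[[`, "activity_fraction"),
                           matrix(0, 6, length(subs)),
                           consts$lambda_phys, consts$lambda_bc,
                           grad_tol, as.integer(max_iter),
                           if (curvature == "expected") 1L else 0L)
  structure(r$value,
            per_subject = stats::setNames(as.numeric(r$per_subject),
                                          vapply(subs, `[[`, "",
                                                 "subject_id")))
}

#' Generic Laplace approximation of a marginal -2 log-likelihood
#'
#' Reference implementation for arbitrary joint -2LL functions of a
#' random-effect vector: finds the mode with [stats::optim()] (BFGS), takes
#' the Hessian by finite differences ([stats::optimHess()]), and returns
#' `joint(mode) + log det( H/2 / (2 pi) )`. The compiled kinetics-specific
#' path ([laplace_subject_neg2ll()]) follows the same convention; this
#' function exists for transparency and for checking that path against
#' models whose marginal likelihood is known in closed form.
#'
#' @param joint_fn Function of the random-effect vector returning the joint
#'   -2LL (including all normalization constants).
#' @param eta_init Numeric starting vector.
#' @param ... Passed to [stats::optim()].
#' @return List with `value`, `eta`, `hessian` (of the joint -2LL),
#'   `converged`.
#' @export
laplace_neg2ll <- function(joint_fn, eta_init, ...) {
  k <- length(eta_init)
  opt <- stats::optim(eta_init, joint_fn, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500L), ...)
  H <- stats::optimHess(opt$par, joint_fn)
  Hhalf <- (H + t(H)) / 4
  ld <- determinant(Hhalf / (2 * pi), logarithm = TRUE)
  if (ld$sign <= 0)
    stop("Hessian at the mode is not positive definite", call. = FALSE)
  list(value = opt$value + as.numeric(ld$modulus),
       eta = opt$par, hessian = H, converged = opt$convergence == 0L)
}
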