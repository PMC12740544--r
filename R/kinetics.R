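#' Physical decay constants for the kinetics model
#'
#' The structural curve carries two fixed, never-estimated rates: the physical
#' decay constant of 177Lu and a fast "blood circulation" uptake rate. Both
#' are derived from half-lives via `ln(2)/T_half` with all times converted to
#' hours, the package-wide time unit.
#'
#' @param t_half_phys_days Physical half-life in days (default 6.6443, 177Lu).
#' @param t_half_bc_min Blood-circulation half-life in minutes (default 1).
#' @return An object of class `ftp_constants`: a list with `t_half_phys_h`,
#'   `lambda_phys`, `t_half_bc_h`, `lambda_bc` (rates in 1/h).
#' @examples
#' cs <- physical_constants()
#' cs$lambda_phys   # ~ 4.35e-3 / h
#' cs$lambda_bc     # ~ 41.6 / h
#' @export
physical_constants <- function(t_half_phys_days = 6.6443, t_half_bc_min = 1) {
  if (!is.numeric(t_half_phys_days) || length(t_half_phys_days) != 1L ||
      t_half_phys_days <= 0)
    stop("'t_half_phys_days' must be a single positive number", call. = FALSE)
  if (!is.numeric(t_half_bc_min) || length(t_half_bc_min) != 1L ||
      t_half_bc_min <= 0)
    stop("'t_half_bc_min' must be a single positive number", call. = FALSE)
  t_phys_h <- t_half_phys_days * 24
  t_bc_h <- t_half_bc_min / 60
  structure(list(
    t_half_phys_h = t_phys_h,
    lambda_phys = decay_constant(t_phys_h),
    t_half_bc_h = t_bc_h,
    lambda_bc = decay_constant(t_bc_h)
  ), class = "ftp_constants")
}

#' Decay constant from a half-life
#'
#' @param half_life_h Half-life in hours; must be positive.
#' @return Rate in 1/h, `log(2)/half_life_h`.
#' @examples
#' decay_constant(6.6443 * 24)  # 177Lu
#' @export
decay_constant <- function(half_life_h) {
  if (!is.numeric(half_life_h) || any(!is.finite(half_life_h)) ||
      any(half_life_h <= 0))
    stop("'half_life_h' must be positive and finite", call. = FALSE)
  log(2) / half_life_h
}

#' @keywords internal
soef_param_names <- function() c("A1", "A2", "A3", "lambda1", "lambda2", "lambda3")

#' Structural kinetic parameters of the sum-of-exponentials curve
#'
#' Validates and packages the six subject-level parameters: prefactors
#' `A1`, `A2`, `A3` (fraction of injected activity) and biological rates
#' `lambda1`, `lambda2`, `lambda3` (1/h). All six must be strictly positive.
#' The implied fourth prefactor `A1 + A2 - A3` is unconstrained; a negative
#' value is physically questionable (the curve can dip below zero early on)
#' and triggers a warning, not an error.
#'
#' @param A1,A2,A3 Prefactors, dimensionless fractions of injected activity.
#' @param lambda1,lambda2,lambda3 Biological uptake/clearance rates in 1/h.
#' @return Named numeric vector of class `soef_params`, in the canonical
#'   order `A1, A2, A3, lambda1, lambda2, lambda3`.
#' @examples
#' soef_params(A1 = 0.02, A2 = 0.01, A3 = 0.025,
#'             lambda1 = 0.005, lambda2 = 0.05, lambda3 = 2)
#' @export
soef_params <- function(A1, A2, A3, lambda1, lambda2, lambda3) {
  p <- c(A1 = A1, A2 = A2, A3 = A3,
         lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3)
  if (!is.numeric(p) || length(p) != 6L || any(!is.finite(p)))
    stop("all six parameters must be finite numbers", call. = FALSE)
  if (any(p <= 0))
    stop("all six parameters must be strictly positive", call. = FALSE)
  if (A1 + A2 - A3 < 0)
    warning("implied fourth prefactor A1 + A2 - A3 is negative; ",
            "the curve goes below zero at early times", call. = FALSE)
  structure(p, class = "soef_params")
}

#' @keywords internal
as_soef_vector <- function(params) {
  if (inherits(params, "soef_params")) return(unclass(params))
  p <- unlist(params, use.names = TRUE)
  if (length(p) != 6L)
    stop("'params' must hold six values (A1, A2, A3, lambda1..3)", call. = FALSE)
  if (!is.null(names(p)) && all(soef_param_names() %in% names(p)))
    p <- p[soef_param_names()]
  if (any(!is.finite(p)) || any(p <= 0))
    stop("structural parameters must be finite and strictly positive",
         call. = FALSE)
  unname(p)
}

#' Evaluate the sum-of-exponentials activity curve
#'
#' Kidney activity as a fraction of injected activity at time `t` hours
#' post-injection:
#' \deqn{f(t) = A_1 e^{-(\lambda_1+\lambda_p)t} + A_2 e^{-(\lambda_2+\lambda_p)t}
#'   - A_3 e^{-(\lambda_3+\lambda_p)t}
#'   - (A_1+A_2-A_3) e^{-(\lambda_{bc}+\lambda_p)t}}
#' The fourth term makes the curve pass exactly through zero at `t = 0`.
#'
#' @param params `soef_params` or a named length-6 numeric vector.
#' @param t Times in hours, non-negative; vectorized.
#' @param consts `physical_constants()` object.
#' @return Numeric vector of activity fractions, same length as `t`.
#' @examples
#' p <- soef_params(0.02, 0.01, 0.025, 0.005, 0.05, 2)
#' soef_eval(p, c(0, 1, 24, 160))
#' @export
soef_eval <- function(params, t, consts = physical_constants()) {
  p <- as_soef_vector(params)
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("'t' must be finite numeric", call. = FALSE)
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  as.numeric(cpp_soef_eval(p, consts$lambda_phys, consts$lambda_bc,
                           as.numeric(t)))
}

#' Analytic time-integrated activity of the curve
#'
#' Integral of [soef_eval()] from 0 to infinity, in units of
#' (fraction of injected activity) x hours:
#' \deqn{TIA = \frac{A_1}{\lambda_1+\lambda_p} + \frac{A_2}{\lambda_2+\lambda_p}
#'   - \frac{A_3}{\lambda_3+\lambda_p}
#'   - \frac{A_1+A_2-A_3}{\lambda_{bc}+\lambda_p}}
#'
#' @inheritParams soef_eval
#' @return TIA in hours (scalar).
#' @examples
#' p <- soef_params(0.02, 0.01, 0.025, 0.005, 0.05, 2)
#' soef_tia(p)
#' @export
soef_tia <- function(params, consts = physical_constants()) {
  p <- as_soef_vector(params)
  lp <- consts$lambda_phys
  unname(p[1] / (p[4] + lp) + p[2] / (p[5] + lp) - p[3] / (p[6] + lp) -
           (p[1] + p[2] - p[3]) / (consts$lambda_bc + lp))
}

#' Gradient of the TIA with respect to the structural parameters
#'
#' Closed-form partial derivatives of [soef_tia()] in the canonical order
#' `(A1, A2, A3, lambda1, lambda2, lambda3)`; used for delta-method
#' uncertainty propagation.
#'
#' @inheritParams soef_eval
#' @return Named numeric vector of length 6.
#' @export
tia_gradient <- function(params, consts = physical_constants()) {
  p <- as_soef_vector(params)
  lp <- consts$lambda_phys
  lbc <- consts$lambda_bc
  g <- c(
    1 / (p[4] + lp) - 1 / (lbc + lp),
    1 / (p[5] + lp) - 1 / (lbc + lp),
    -1 / (p[6] + lp) + 1 / (lbc + lp),
    -p[1] / (p[4] + lp)^2,
    -p[2] / (p[5] + lp)^2,
    p[3] / (p[6] + lp)^2
  )
  names(g) <- soef_param_names()
  g
}

#' Delta-method standard deviation of the TIA
#'
#' First-order propagation of a parameter covariance matrix through the
#' analytic TIA: `sqrt(g' C g)` with `g = tia_gradient(params)`.
#'
#' @inheritParams soef_eval
#' @param param_cov Symmetric positive semidefinite 6x6 covariance of the
#'   structural parameters, in canonical order.
#' @return SD of the TIA in hours.
#' @export
tia_sd_delta <- function(params, param_cov, consts = physical_constants()) {
  if (!is.matrix(param_cov) || any(dim(param_cov) != c(6L, 6L)))
    stop("'param_cov' must be a 6x6 matrix", call. = FALSE)
  if (any(!is.finite(param_cov)))
    stop("'param_cov' must be finite", call. = FALSE)
  if (max(abs(param_cov - t(param_cov))) >
      1e-8 * max(abs(param_cov), 1e-300))
    stop("'param_cov' must be symmetric", call. = FALSE)
  g <- tia_gradient(params, consts)
  v <- drop(t(g) %*% param_cov %*% g)
  if (v < 0) {
    if (v < -1e-10 * max(abs(param_cov)))
      stop("'param_cov' is not positive semidefinite along the TIA gradient",
           call. = FALSE)
    v <- 0
  }
  sqrt(v)
}
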