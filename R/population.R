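#' Population (mixed-effects) model specification
#'
#' Bundles the population-level quantities of the kinetics model: typical
#' values `theta` (fixed effects, same semantics and units as
#' [soef_params()]), diagonal inter-individual variances `omega` of the
#' log-scale random effects, and the residual error magnitude `sigma`.
#' Individual parameters are `theta * exp(eta)` with
#' `eta ~ N(0, diag(omega))`, so positivity is guaranteed by construction.
#'
#' The residual model is selected by `error_model`:
#' * `"proportional"` (default): `y ~ N(f, (sigma * f)^2)`, `sigma` a fraction;
#' * `"additive"`: `y ~ N(f, sigma^2)`, `sigma` on the activity scale;
#' * `"combined"`: `sigma = c(prop, add)`, variance `add^2 + (prop * f)^2`.
#'
#' With a single residual term the model exposes 6 + 6 + 1 = 13 estimated
#' quantities (see [n_parameters()]).
#'
#' @param theta Named or ordered length-6 vector of typical values, all > 0.
#' @param omega Length-6 vector of random-effect variances, all >= 0.
#'   An entry of 0 fixes that random effect at zero (point mass).
#' @param sigma Residual error magnitude(s); length 1, or 2 for `"combined"`.
#' @param error_model One of `"proportional"`, `"additive"`, `"combined"`.
#' @return Object of class `population_model`.
#' @examples
#' population_model(theta = c(0.02, 0.01, 0.025, 0.005, 0.05, 2),
#'                  omega = rep(0.09, 6), sigma = 0.1)
#' @export
population_model <- function(theta, omega, sigma,
                             error_model = c("proportional", "additive",
                                             "combined")) {
  error_model <- match.arg(error_model)
  theta <- as_soef_vector(theta)
  if (!is.numeric(omega) || length(omega) != 6L || any(!is.finite(omega)) ||
      any(omega < 0))
    stop("'omega' must be six finite non-negative variances", call. = FALSE)
  n_sig <- if (error_model == "combined") 2L else 1L
  if (!is.numeric(sigma) || length(sigma) != n_sig || any(!is.finite(sigma)) ||
      any(sigma <= 0))
    stop(sprintf("'sigma' must be %d positive value(s) for the %s error model",
                 n_sig, error_model), call. = FALSE)
  structure(list(
    theta = stats::setNames(unname(theta), soef_param_names()),
    omega = stats::setNames(as.numeric(omega), soef_param_names()),
    sigma = as.numeric(sigma),
    error_model = error_model
  ), class = "population_model")
}

#' Number of estimated quantities of a population model
#'
#' Six fixed effects plus six (diagonal) inter-individual variances plus the
#' residual error term(s): 13 for the single-sigma error models.
#'
#' @param model A [population_model()].
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "population_model"))
  6L + 6L + length(model$sigma)
}

#' Individual parameters from typical values and random effects
#'
#' The log-normal individual map `params_j = theta_j * exp(eta_j)`.
#'
#' @param theta Length-6 positive typical values.
#' @param eta Length-6 random effects (log scale).
#' @return `soef_params` vector.
#' @examples
#' individual_params(c(0.02, 0.01, 0.025, 0.005, 0.05, 2), rep(0, 6))
#' @export
individual_params <- function(theta, eta) {
  theta <- as_soef_vector(theta)
  if (!is.numeric(eta) || length(eta) != 6L || any(!is.finite(eta)))
    stop("'eta' must be six finite numbers", call. = FALSE)
  p <- theta * exp(as.numeric(eta))
  # positivity holds by construction; the sign of A1+A2-A3 is unconstrained,
  # so no validation warning here (see soef_params for the user-facing check)
  structure(stats::setNames(p, soef_param_names()), class = "soef_params")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population kinetics model (", x$error_model, " residual error)\n",
      sep = "")
  cat("  theta:", paste(sprintf("%s=%.4g", names(x$theta), x$theta),
                        collapse = ", "), "\n")
  cat("  omega:", paste(sprintf("%.4g", x$omega), collapse = ", "), "\n")
  cat("  sigma:", paste(sprintf("%.4g", x$sigma), collapse = ", "), "\n")
  cat("  estimated quantities:", n_parameters(x), "\n")
  invisible(x)
}

# residual variance pieces (s2a additive, s2p proportional) for the C++ core
#' @keywords internal
error_variances <- function(model) {
  switch(model$error_model,
         proportional = c(s2a = 0, s2p = model$sigma[1]^2),
         additive     = c(s2a = model$sigma[1]^2, s2p = 0),
         combined     = c(s2a = model$sigma[2]^2, s2p = model$sigma[1]^2))
}
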