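#' Model parameters for the diabetes-complications (DC) model
#'
#' Constructs and validates the full parameterization of the two-compartment
#' DC model: the population of diagnosed diabetics is split into those with
#' complications, `C(t)`, and those without, `D(t)`; `N(t) = C(t) + D(t)` is
#' the total stock. All rates are per year; `incidence` is the constant
#' inflow of newly diagnosed cases (persons/year), entering both compartment
#' balances.
#'
#' @param lambda probability (rate) of developing a complication, per year.
#' @param delta mortality rate due to complications, per year.
#' @param mu natural mortality rate, per year.
#' @param gamma rate at which complications are controlled, per year.
#' @param nu rate of becoming severely disabled, per year.
#' @param incidence new diabetes cases per year (persons/yr).
#'
#' @details All six values must be finite and non-negative, and at least one
#'   of `mu`, `delta`, `nu` must be positive; otherwise the system has no
#'   outflow and no finite equilibrium. The composite outflow rate
#'   `theta = gamma + mu + nu + delta` must be positive. In the closed-form
#'   solution literature for this model the transfer rate is written `rho`;
#'   here `rho` is an alias for `lambda` (see [dc_derived()]).
#'
#' @return An object of class `dc_params`: a named list with the six fields.
#' @seealso [dc_default_params()] for the canonical parameter set,
#'   [dc_derived()] for the composite constants.
#' @export
#' @examples
#' p <- dc_params(lambda = 0.85, delta = 0.05, mu = 0.02,
#'                gamma = 0.5, nu = 0.05, incidence = 6e6)
#' p
dc_params <- function(lambda, delta, mu, gamma, nu, incidence) {
  vals <- c(lambda = lambda, delta = delta, mu = mu,
            gamma = gamma, nu = nu, incidence = incidence)
  if (!all(is.finite(vals))) {
    stop("all parameters must be finite numbers", call. = FALSE)
  }
  if (any(vals < 0)) {
    bad <- names(vals)[vals < 0][1L]
    stop(sprintf("parameter '%s' must be >= 0", bad), call. = FALSE)
  }
  if (mu + delta + nu <= 0) {
    stop("at least one of mu, delta, nu must be positive (no outflow otherwise)",
         call. = FALSE)
  }
  if (gamma + mu + nu + delta <= 0) {
    stop("theta = gamma + mu + nu + delta must be positive", call. = FALSE)
  }
  structure(as.list(vals), class = "dc_params")
}

#' @export
print.dc_params <- function(x, ...) {
  cat("DC model parameters (per year):\n")
  cat(sprintf("  lambda (complication rate)      %g\n", x$lambda))
  cat(sprintf("  delta  (complication mortality) %g\n", x$delta))
  cat(sprintf("  mu     (natural mortality)      %g\n", x$mu))
  cat(sprintf("  gamma  (complication control)   %g\n", x$gamma))
  cat(sprintf("  nu     (severe disability)      %g\n", x$nu))
  cat(sprintf("  incidence                       %g persons/yr\n", x$incidence))
  invisible(x)
}

#' Composite rate constants of the DC model
#'
#' Computes the composite constants that govern the closed-form solution:
#' the outflow rate `theta = gamma + mu + nu + delta`, the trace-like sum
#' `sigma = rho + theta + mu`, the determinant-like product
#' `beta = rho*(nu + delta) + mu*(rho + theta)`, the forcing coefficient
#' `alpha = 2*rho + mu`, and the two modal decay rates `eta1 <= eta2`
#' (1/yr), the roots of `x^2 - sigma*x + beta = 0`:
#' `eta = (sigma -+ sqrt(sigma^2 - 4*beta)) / 2`.
#' Throughout, `rho` denotes the complication transfer rate and equals
#' `lambda`.
#'
#' @param params a [dc_params()] object.
#' @return A list of class `dc_derived` with fields `theta`, `sigma`,
#'   `beta`, `alpha`, `eta1`, `eta2`.
#' @details The decay rates are real iff `sigma^2 >= 4*beta`; for complex
#'   modes (never reached for non-negative rates of this model, but guarded
#'   anyway) the function signals an error of class `dcmodel_complex_modes`
#'   and the spiral/centre cases are handled by [dc_stability()].
#' @export
dc_derived <- function(params) {
  stopifnot(inherits(params, "dc_params"))
  rho <- params$lambda
  theta <- params$gamma + params$mu + params$nu + params$delta
  sigma <- rho + theta + params$mu
  beta <- rho * (params$nu + params$delta) + params$mu * (rho + theta)
  alpha <- 2 * rho + params$mu
  rad <- sigma^2 - 4 * beta
  if (rad < 0) {
    stop(structure(class = c("dcmodel_complex_modes", "error", "condition"),
                   list(message = "sigma^2 < 4*beta: modes are complex; use dc_stability()",
                        call = sys.call(-1))))
  }
  s <- sqrt(rad)
  structure(list(theta = theta, sigma = sigma, beta = beta, alpha = alpha,
                 eta1 = (sigma - s) / 2, eta2 = (sigma + s) / 2),
            class = "dc_derived")
}

#' System matrix and forcing vector of the (C, N) formulation
#'
#' The model in the `(C, N)` variables is the affine linear system
#' `d/dt (C, N) = A (C, N) + b` with
#' `A = [[-(lambda+theta), lambda], [-(nu+delta), -mu]]` and
#' `b = (I, 2I)`.
#'
#' @param params a [dc_params()] object.
#' @return list with `A` (2x2 matrix, rows/cols named C, N) and `b`
#'   (length-2 forcing, persons/yr).
#' @export
dc_system_matrix <- function(params) {
  theta <- params$gamma + params$mu + params$nu + params$delta
  A <- matrix(c(-(params$lambda + theta), -(params$nu + params$delta),
                params$lambda, -params$mu),
              nrow = 2, dimnames = list(c("C", "N"), c("C", "N")))
  list(A = A, b = c(C = params$incidence, N = 2 * params$incidence))
}

#' Read DC model parameters from a flat config file
#'
#' Parses a flat YAML (or JSON, which YAML subsumes) key-value file with
#' keys `lambda`, `delta`, `mu`, `gamma`, `nu`, `incidence`. Missing keys
#' fall back to the canonical defaults of [dc_default_params()]; unknown
#' keys are an error so that typos cannot silently revert a parameter to
#' its default.
#'
#' @param path path to the config file; an empty or absent-of-keys file
#'   yields the full default set.
#' @return a [dc_params()] object.
#' @export
dc_read_params <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  }
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop(sprintf(
                    "cannot parse config '%s': %s", path, conditionMessage(e)),
                    call. = FALSE))
  if (is.null(raw)) raw <- list()
  allowed <- c("lambda", "delta", "mu", "gamma", "nu", "incidence")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  defaults <- unclass(dc_default_params())
  merged <- utils::modifyList(defaults, raw[intersect(names(raw), allowed)])
  do.call(dc_params, merged)
}

#' Write DC model parameters to a flat config file
#'
#' Inverse of [dc_read_params()]; the round trip is the identity.
#'
#' @param params a [dc_params()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
dc_write_params <- function(params, path) {
  stopifnot(inherits(params, "dc_params"))
  yaml::write_yaml(unclass(params), path, precision = 15L)
  invisible(path)
}
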