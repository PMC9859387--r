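#' Construct a model state
#'
#' A state is a time-stamped pair `(C, N)`: diabetics with complications and
#' total diabetics, in persons. The derived compartment `D = N - C` and a
#' `valid` flag are carried along; numerical schemes may legitimately
#' produce states with `C < 0` or `N < C`, which the flag records rather
#' than forbids.
#'
#' @param t time in years (>= 0).
#' @param C diabetics with complications (persons).
#' @param N total diabetics (persons).
#' @return list of class `dc_state` with fields `t`, `C`, `N`, `D`, `valid`.
#' @export
dc_state <- function(t, C, N) {
  stopifnot(is.finite(t), t >= 0, is.numeric(C), is.numeric(N))
  t <- unname(t); C <- unname(C); N <- unname(N)
  structure(list(t = t, C = C, N = N, D = N - C,
                 valid = is.finite(C) && is.finite(N) && C >= 0 && N >= C),
            class = "dc_state")
}

#' @export
print.dc_state <- function(x, ...) {
  cat(sprintf("DC state at t = %g yr: C = %.2f, N = %.2f (D = %.2f)%s\n",
              x$t, x$C, x$N, x$D, if (x$valid) "" else " [invalid]"))
  invisible(x)
}

#' Right-hand side of the DC model in (C, N) variables
#'
#' Evaluates the time derivatives
#' \deqn{C'(t) = I - (\lambda+\theta) C + \lambda N}
#' \deqn{N'(t) = 2I - (\nu+\delta) C - \mu N}
#' with `theta = gamma + mu + nu + delta`. These are the equations the
#' solvers discretize and the exact propagator solves.
#'
#' @param state a [dc_state()] (only `C` and `N` are used).
#' @param params a [dc_params()] object.
#' @return named numeric vector `c(dC, dN)` in persons/yr.
#' @export
dc_rhs <- function(state, params) {
  theta <- params$gamma + params$mu + params$nu + params$delta
  c(dC = params$incidence - (params$lambda + theta) * state$C +
      params$lambda * state$N,
    dN = 2 * params$incidence - (params$nu + params$delta) * state$C -
      params$mu * state$N)
}

#' Right-hand side in the original (D, C) compartment variables
#'
#' The two-compartment form:
#' \deqn{D'(t) = I - (\lambda+\mu) D + \gamma C}
#' \deqn{C'(t) = I + \lambda D - (\gamma+\mu+\nu+\delta) C}
#' Incidence enters both balances (newly diagnosed cases may already carry
#' complications), so `D' + C'` equals the `N'` of [dc_rhs()] with
#' `N = D + C` — an identity the test suite asserts.
#'
#' @param D diabetics without complications (persons).
#' @param C diabetics with complications (persons).
#' @param params a [dc_params()] object.
#' @return named numeric vector `c(dD, dC)` in persons/yr.
#' @export
dc_rhs_dc <- function(D, C, params) {
  theta <- params$gamma + params$mu + params$nu + params$delta
  c(dD = params$incidence - (params$lambda + params$mu) * D + params$gamma * C,
    dC = params$incidence + params$lambda * D - theta * C)
}

#' Equilibrium (critical point) of the DC model
#'
#' @param params a [dc_params()] object.
#' @param variant `"ode_consistent"` (default) solves the 2x2 linear system
#'   `A x + b = 0` exactly, so both derivatives vanish at the returned
#'   point. `"literature_formula"` evaluates the closed-form expressions
#'   `C* = (2 rho + mu) I / (rho (nu + delta + mu) + mu theta)` and
#'   `N* = (2 (rho + theta) - (mu + delta)) I / (rho (nu + delta + mu) + mu theta)`
#'   found in the source literature for this model; the two variants agree
#'   on `C*` algebraically (the denominator equals `beta`) but not on `N*`,
#'   whose literature formula is not a root of the system.
#' @return list of class `dc_equilibrium` with `C_star`, `N_star`,
#'   `variant`.
#' @details Requires `beta > 0`; at `beta = 0` the system matrix is
#'   singular and an error of class `dcmodel_singular` is signalled.
#' @export
dc_equilibrium <- function(params, variant = c("ode_consistent", "literature_formula")) {
  variant <- match.arg(variant)
  d <- dc_derived(params)
  if (d$beta <= 0) {
    stop(structure(class = c("dcmodel_singular", "error", "condition"),
                   list(message = "beta = 0: system matrix singular, no unique equilibrium",
                        call = sys.call(-1))))
  }
  if (variant == "ode_consistent") {
    sys <- dc_system_matrix(params)
    x <- solve(sys$A, -sys$b)
    out <- list(C_star = unname(x[1]), N_star = unname(x[2]), variant = variant)
  } else {
    rho <- params$lambda
    den <- rho * (params$nu + params$delta + params$mu) + params$mu * d$theta
    out <- list(
      C_star = (2 * rho + params$mu) * params$incidence / den,
      N_star = (2 * (rho + d$theta) - (params$mu + params$delta)) *
        params$incidence / den,
      variant = variant)
  }
  structure(out, class = "dc_equilibrium")
}

#' Initial conditions as an offset from the equilibrium
#'
#' The customary initial state for this model is the equilibrium displaced
#' by a few hundred persons in each coordinate (+/- 500 by convention).
#'
#' @param params a [dc_params()] object.
#' @param offset_C displacement of `C` from `C*` (persons); default +500.
#' @param offset_N displacement of `N` from `N*` (persons); default +500.
#' @return a [dc_state()] at `t = 0`.
#' @export
dc_initial_state <- function(params, offset_C = 500, offset_N = 500) {
  eq <- dc_equilibrium(params, "ode_consistent")
  dc_state(0, eq$C_star + offset_C, eq$N_star + offset_N)
}
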