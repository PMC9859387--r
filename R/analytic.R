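#' Closed-form mode amplitudes for the DC model
#'
#' The solution of the (C, N) system with distinct decay rates
#' `eta1 != eta2` is
#' \deqn{C(t) = K_1 e^{-\eta_1 t} + K_2 e^{-\eta_2 t} + (\alpha/\beta) I}
#' with the amplitudes fixed by the initial state:
#' \deqn{K_1 = \frac{\beta(\rho+\theta-\eta_2)C_0 + I(\alpha\eta_2-\beta) - \rho\beta N_0}{\beta(\eta_1-\eta_2)}}
#' and `K2` the mirror expression with `eta1` and `eta2` exchanged and the
#' overall sign flipped (`rho = lambda` throughout). By construction
#' `K1 + K2 + C_inf = C0` exactly, where `C_inf = (alpha/beta) I` is the
#' asymptote (and equals the equilibrium `C*`).
#'
#' @param params a [dc_params()] object.
#' @param C0,N0 initial compartment sizes (persons) at the anchor time.
#' @return list of class `dc_coeffs` with `K1`, `K2`, `C_inf` and the
#'   derived constants used.
#' @details Signals an error of class `dcmodel_degenerate_spectrum` when
#'   `eta1 == eta2` (repeated root, not covered by the two-exponential
#'   form; [dc_propagate()] handles it).
#' @export
dc_analytic_coefficients <- function(params, C0, N0) {
  d <- dc_derived(params)
  if (d$eta1 == d$eta2) {
    stop(structure(class = c("dcmodel_degenerate_spectrum", "error", "condition"),
                   list(message = "eta1 == eta2: repeated root; use dc_propagate()",
                        call = sys.call(-1))))
  }
  rho <- params$lambda
  I <- params$incidence
  beta <- d$beta
  den <- beta * (d$eta1 - d$eta2)
  K1 <- (beta * (rho + d$theta - d$eta2) * C0 + I * (d$alpha * d$eta2 - beta) -
           rho * beta * N0) / den
  K2 <- -(beta * (rho + d$theta - d$eta1) * C0 + I * (d$alpha * d$eta1 - beta) -
            rho * beta * N0) / den
  structure(list(K1 = K1, K2 = K2, C_inf = d$alpha / beta * I, derived = d,
                 params = params),
            class = "dc_coeffs")
}

#' Closed-form C(t)
#'
#' Evaluates the two-exponential solution for the complications compartment
#' at times `t` (years since the anchor of the coefficients).
#'
#' @param coeffs a [dc_analytic_coefficients()] object.
#' @param t numeric vector of non-negative times.
#' @return persons, same length as `t`.
#' @export
dc_analytic_C <- function(coeffs, t) {
  stopifnot(inherits(coeffs, "dc_coeffs"), all(t >= 0))
  d <- coeffs$derived
  coeffs$K1 * exp(-d$eta1 * t) + coeffs$K2 * exp(-d$eta2 * t) + coeffs$C_inf
}

#' Closed-form N(t)
#'
#' Obtained by substituting the closed-form `C(t)` into the first model
#' equation, `N(t) = (C'(t) + (lambda+theta) C(t) - I) / lambda`, which
#' gives
#' \deqn{N(t) = \frac{(\lambda+\theta-\eta_1)K_1 e^{-\eta_1 t} + (\lambda+\theta-\eta_2)K_2 e^{-\eta_2 t} + (\lambda+\theta)C_\infty - I}{\lambda}.}
#' This form satisfies both differential equations jointly with
#' [dc_analytic_C()] by construction.
#'
#' @param coeffs a [dc_analytic_coefficients()] object.
#' @param t numeric vector of non-negative times.
#' @return persons, same length as `t`.
#' @details Requires `lambda > 0`; with `lambda = 0` the C equation
#'   decouples from N and this substitution is undefined (error class
#'   `dcmodel_lambda_zero`); integrate the N equation directly, e.g. via
#'   [dc_propagate()].
#' @export
dc_analytic_N <- function(coeffs, t) {
  stopifnot(inherits(coeffs, "dc_coeffs"), all(t >= 0))
  p <- coeffs$params
  if (p$lambda <= 0) {
    stop(structure(class = c("dcmodel_lambda_zero", "error", "condition"),
                   list(message = "lambda = 0: N(t) not recoverable from C(t); use dc_propagate()",
                        call = sys.call(-1))))
  }
  d <- coeffs$derived
  a <- p$lambda + d$theta
  ((a - d$eta1) * coeffs$K1 * exp(-d$eta1 * t) +
     (a - d$eta2) * coeffs$K2 * exp(-d$eta2 * t) +
     a * coeffs$C_inf - p$incidence) / p$lambda
}

#' Exact propagation of the DC model
#'
#' Advances a state by `delta_t` years using the exact solution of the
#' affine linear system: the deviation from the equilibrium is decomposed
#' on the eigenbasis of the system matrix and each mode is scaled by
#' `exp(eigenvalue * delta_t)`. This is the truth oracle against which all
#' numerical trajectories are scored. The semigroup property
#' `propagate(s, a + b) == propagate(propagate(s, a), b)` holds to
#' round-off.
#'
#' @param state a [dc_state()].
#' @param delta_t years to advance (>= 0).
#' @param params a [dc_params()] object.
#' @return the advanced [dc_state()].
#' @details A repeated eigenvalue (defective or not) is handled through the
#'   2x2 matrix-exponential identity
#'   `exp(A t) = exp(l t) (I + (A - l I) t)`, covering the `t e^{-l t}`
#'   secular term. Complex pairs are handled by the same eigendecomposition
#'   in complex arithmetic; the result is real.
#' @export
dc_propagate <- function(state, delta_t, params) {
  stopifnot(inherits(state, "dc_state"), delta_t >= 0)
  sys <- dc_system_matrix(params)
  x <- c(state$C, state$N)
  xstar <- solve(sys$A, -sys$b)
  dev <- x - xstar
  ev <- eigen(sys$A)
  if (abs(ev$values[1] - ev$values[2]) <=
      1e-9 * max(abs(ev$values), .Machine$double.eps)) {
    l <- mean(Re(ev$values))
    E <- exp(l * delta_t) *
      (diag(2) + (sys$A - l * diag(2)) * delta_t)
    new_dev <- as.numeric(E %*% dev)
  } else {
    z <- solve(ev$vectors, dev)
    new_dev <- Re(as.numeric(ev$vectors %*% (exp(ev$values * delta_t) * z)))
  }
  dc_state(state$t + delta_t, xstar[1] + new_dev[1], xstar[2] + new_dev[2])
}
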