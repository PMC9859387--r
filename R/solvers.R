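#' @name dc_steppers
#' @rdname dc_steppers
#' @title Single fixed-length steps of the five numerical schemes
#'
#' @description One step of each scheme applied to the (C, N) system.
#' All steppers hold the equilibrium exactly fixed (it is a fixed point of
#' every consistent discretization of an autonomous system) and reduce to
#' their textbook scalar forms when the coupling is switched off.
#'
#' * `dc_step_explicit_euler()` — forward Euler, order 1.
#' * `dc_step_implicit_euler()` — backward Euler, order 1, A-stable. The
#'   two update equations are mutually coupled (each new value appears in
#'   the other's update), so the step solves the 2x2 linear system
#'   `(I - dt*A) x_new = x + dt*b` exactly. `gauss_seidel = TRUE` instead
#'   performs one sweep with lagged coupling (C updated from the old N,
#'   then N from the new C), kept for fidelity experiments with the
#'   sequential-update reading of the scheme.
#' * `dc_step_heun()` — explicit-Euler predictor, trapezoidal corrector
#'   averaging the derivative at the current state and at the predictor;
#'   order 2.
#' * `dc_step_rk4()` — classical fourth-order Runge-Kutta: half-increment
#'   stages 2 and 3, full increment in stage 4.
#' * `dc_step_abm4()` — four-step Adams-Bashforth predictor, derivative
#'   re-evaluation at the predictor, three-step Adams-Moulton corrector
#'   (PECE); needs exactly four equally spaced history states.
#'
#' @param state a [dc_state()].
#' @param dt step size in years (> 0).
#' @param params a [dc_params()] object.
#' @param gauss_seidel logical; see Description (implicit Euler only).
#' @param history for `dc_step_abm4()`: a list of the last four
#'   [dc_state()]s, oldest first, spaced `dt` apart.
#' @return the advanced [dc_state()].
NULL

.dc_rhs_xy <- function(x, params, theta) {
  c(params$incidence - (params$lambda + theta) * x[1] + params$lambda * x[2],
    2 * params$incidence - (params$nu + params$delta) * x[1] -
      params$mu * x[2])
}

#' @rdname dc_steppers
#' @export
dc_step_explicit_euler <- function(state, dt, params) {
  stopifnot(dt > 0)
  theta <- params$gamma + params$mu + params$nu + params$delta
  x <- c(state$C, state$N)
  x <- x + dt * .dc_rhs_xy(x, params, theta)
  dc_state(state$t + dt, x[1], x[2])
}

#' @rdname dc_steppers
#' @export
dc_step_implicit_euler <- function(state, dt, params, gauss_seidel = FALSE) {
  stopifnot(dt > 0)
  if (gauss_seidel) {
    theta <- params$gamma + params$mu + params$nu + params$delta
    Cn <- (dt * (params$incidence + params$lambda * state$N) + state$C) /
      (1 + dt * (params$lambda + theta))
    Nn <- (dt * (2 * params$incidence - Cn * (params$nu + params$delta)) +
             state$N) / (1 + dt * params$mu)
    return(dc_state(state$t + dt, Cn, Nn))
  }
  sys <- dc_system_matrix(params)
  M <- diag(2) - dt * sys$A
  if (abs(det(M)) < .Machine$double.eps) {
    stop(structure(class = c("dcmodel_singular_step", "error", "condition"),
                   list(message = "implicit-step matrix singular",
                        call = sys.call(-1))))
  }
  x <- solve(M, c(state$C, state$N) + dt * sys$b)
  dc_state(state$t + dt, x[1], x[2])
}

#' @rdname dc_steppers
#' @export
dc_step_heun <- function(state, dt, params) {
  stopifnot(dt > 0)
  theta <- params$gamma + params$mu + params$nu + params$delta
  x <- c(state$C, state$N)
  f0 <- .dc_rhs_xy(x, params, theta)
  pred <- x + dt * f0
  x <- x + dt / 2 * (f0 + .dc_rhs_xy(pred, params, theta))
  dc_state(state$t + dt, x[1], x[2])
}

#' @rdname dc_steppers
#' @export
dc_step_rk4 <- function(state, dt, params) {
  stopifnot(dt > 0)
  theta <- params$gamma + params$mu + params$nu + params$delta
  x <- c(state$C, state$N)
  k1 <- .dc_rhs_xy(x, params, theta)
  k2 <- .dc_rhs_xy(x + dt / 2 * k1, params, theta)
  k3 <- .dc_rhs_xy(x + dt / 2 * k2, params, theta)
  k4 <- .dc_rhs_xy(x + dt * k3, params, theta)
  x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  dc_state(state$t + dt, x[1], x[2])
}

#' @rdname dc_steppers
#' @export
dc_step_abm4 <- function(history, dt, params) {
  stopifnot(dt > 0)
  if (!is.list(history) || length(history) != 4 ||
      !all(vapply(history, inherits, logical(1), "dc_state"))) {
    stop(structure(class = c("dcmodel_insufficient_history", "error", "condition"),
                   list(message = "dc_step_abm4 needs exactly 4 dc_state history entries",
                        call = sys.call(-1))))
  }
  ts <- vapply(history, `[[`, numeric(1), "t")
  if (max(abs(diff(ts) - dt)) > 1e-9 * max(dt, 1)) {
    stop(structure(class = c("dcmodel_insufficient_history", "error", "condition"),
                   list(message = "history states must be spaced dt apart",
                        call = sys.call(-1))))
  }
  theta <- params$gamma + params$mu + params$nu + params$delta
  xs <- lapply(history, function(s) c(s$C, s$N))
  fs <- lapply(xs, .dc_rhs_xy, params = params, theta = theta)
  # predictor (Adams-Bashforth, 4-step), then PECE corrector (Adams-Moulton)
  xp <- xs[[4]] + dt / 24 *
    (55 * fs[[4]] - 59 * fs[[3]] + 37 * fs[[2]] - 9 * fs[[1]])
  fp <- .dc_rhs_xy(xp, params, theta)
  x <- xs[[4]] + dt / 24 * (9 * fp + 19 * fs[[4]] - 5 * fs[[3]] + fs[[2]])
  dc_state(history[[4]]$t + dt, x[1], x[2])
}

#' Fixed-step integration of the DC model
#'
#' Integrates from `state0` to `t_end` on a uniform grid of spacing `dt`
#' with the chosen scheme. The Adams-Bashforth-Moulton scheme is
#' bootstrapped with three RK4 steps and then applied in a sliding
#' four-state window; `method = "analytic"` delegates every step to the
#' exact propagator [dc_propagate()].
#'
#' @param method one of `"explicit_euler"`, `"implicit_euler"`, `"heun"`,
#'   `"rk4"`, `"abm4"`, `"analytic"`.
#' @param state0 initial [dc_state()].
#' @param params a [dc_params()] object.
#' @param dt step size in years (> 0).
#' @param t_end final time; must equal `state0$t + k*dt` for integer k.
#' @param divergence_threshold persons; a step whose `|C|` or `|N|` exceeds
#'   it (or goes non-finite) marks the trajectory diverged and stops the
#'   run. The default, 1e12, is more than a thousand times the population
#'   scale of any stable run.
#' @return A `dc_trajectory`: a data.frame with columns `t`, `C`, `N`, `D`
#'   and attributes `method`, `dt`, `diverged` (logical) and `t_diverged`
#'   (NA when the run completed).
#' @export
#' @examples
#' p <- dc_default_params()
#' s0 <- dc_initial_state(p, 500, 500)
#' tr <- dc_integrate("rk4", s0, p, dt = 1, t_end = 20)
#' tail(tr, 3)
dc_integrate <- function(method, state0, params, dt, t_end,
                         divergence_threshold = 1e12) {
  method <- match.arg(method, c("explicit_euler", "implicit_euler", "heun",
                                "rk4", "abm4", "analytic"))
  stopifnot(inherits(state0, "dc_state"), dt > 0, t_end >= state0$t)
  n_steps <- (t_end - state0$t) / dt
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    stop("t_end must lie on the step grid (state0$t + k*dt)", call. = FALSE)
  }
  n_steps <- as.integer(round(n_steps))
  states <- vector("list", n_steps + 1L)
  states[[1L]] <- state0
  diverged <- FALSE
  t_diverged <- NA_real_
  stepper <- switch(method,
    explicit_euler = dc_step_explicit_euler,
    implicit_euler = dc_step_implicit_euler,
    heun = dc_step_heun,
    rk4 = dc_step_rk4,
    analytic = function(s, dt, p) dc_propagate(s, dt, p),
    abm4 = NULL)
  i <- 1L
  while (i <= n_steps) {
    s <- if (method == "abm4" && i >= 4L) {
      dc_step_abm4(states[(i - 3L):i], dt, params)
    } else if (method == "abm4") {
      dc_step_rk4(states[[i]], dt, params)  # bootstrap
    } else {
      stepper(states[[i]], dt, params)
    }
    states[[i + 1L]] <- s
    if (!is.finite(s$C) || !is.finite(s$N) ||
        abs(s$C) > divergence_threshold || abs(s$N) > divergence_threshold) {
      diverged <- TRUE
      t_diverged <- s$t
      states <- states[seq_len(i + 1L)]
      break
    }
    i <- i + 1L
  }
  out <- data.frame(
    t = vapply(states, `[[`, numeric(1), "t"),
    C = vapply(states, `[[`, numeric(1), "C"),
    N = vapply(states, `[[`, numeric(1), "N"))
  out$D <- out$N - out$C
  structure(out, method = method, dt = dt, diverged = diverged,
            t_diverged = t_diverged,
            class = c("dc_trajectory", "data.frame"))
}

#' Per-mode amplification factors of a scheme
#'
#' For a linear system with decay rates `eta1`, `eta2`, each one-step
#' scheme multiplies the corresponding mode by its stability function
#' evaluated at `x = dt * eta`: `1 - x` for explicit Euler, `1/(1 + x)`
#' for implicit Euler, `1 - x + x^2/2` for Heun, the quartic Taylor
#' polynomial of `exp(-x)` for RK4, and `exp(-x)` exactly for the analytic
#' propagator. For the four-step Adams-Bashforth-Moulton PECE scheme the
#' factor is the largest-magnitude root of its characteristic polynomial.
#' A scheme is numerically stable at `dt` when the spectral radius (the
#' larger of the two per-mode magnitudes) does not exceed 1.
#'
#' @param method scheme tag as in [dc_integrate()].
#' @param params a [dc_params()] object.
#' @param dt step size in years (> 0).
#' @return list of class `dc_amplification` with `method`, `dt`, `factors`
#'   (named by mode), `spectral_radius`, `stable`.
#' @export
dc_amplification <- function(method, params, dt) {
  method <- match.arg(method, c("explicit_euler", "implicit_euler", "heun",
                                "rk4", "abm4", "analytic"))
  stopifnot(dt > 0)
  d <- dc_derived(params)
  xs <- dt * c(eta1 = d$eta1, eta2 = d$eta2)
  fac <- switch(method,
    explicit_euler = 1 - xs,
    implicit_euler = 1 / (1 + xs),
    heun = 1 - xs + xs^2 / 2,
    rk4 = 1 - xs + xs^2 / 2 - xs^3 / 6 + xs^4 / 24,
    analytic = exp(-xs),
    abm4 = vapply(xs, .dc_abm4_root, numeric(1)))
  names(fac) <- names(xs)
  radius <- max(abs(fac))
  structure(list(method = method, dt = dt, factors = fac,
                 spectral_radius = radius,
                 stable = radius <= 1 + 1e-12),
            class = "dc_amplification")
}

# largest-magnitude root of the ABM4 PECE characteristic polynomial for
# y' = -eta*y at x = dt*eta:
#   r^4 + (-1 + 28q - 495q^2) r^3 + (-5q + 531q^2) r^2
#       + (q - 333q^2) r + 81q^2 = 0,  q = x/24
.dc_abm4_root <- function(x) {
  q <- x / 24
  co <- c(81 * q^2, q - 333 * q^2, -5 * q + 531 * q^2,
          -1 + 28 * q - 495 * q^2, 1)
  max(Mod(polyroot(co)))
}

#' @export
print.dc_amplification <- function(x, ...) {
  cat(sprintf("%s at dt = %g yr: factors (%.6g, %.6g), spectral radius %.6g -> %s\n",
              x$method, x$dt, x$factors[1], x$factors[2], x$spectral_radius,
              if (x$stable) "stable" else "unstable"))
  invisible(x)
}
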