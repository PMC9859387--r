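#' Percentage error against a truth value
#'
#' `|num - truth| / |truth| * 100`, the error measure of all the error
#' tables.
#'
#' @param num numeric value(s).
#' @param truth reference value(s), nonzero.
#' @return percentage error(s).
#' @export
dc_pct_error <- function(num, truth) {
  if (any(truth == 0)) {
    stop(structure(class = c("dcmodel_zero_truth", "error", "condition"),
                   list(message = "percentage error undefined for truth = 0",
                        call = sys.call(-1))))
  }
  abs(num - truth) / abs(truth) * 100
}

#' Numeric-versus-true error table for one scheme
#'
#' Runs the chosen scheme from `anchor_state` with step `dt` and compares
#' `C` and `N` against exact propagation at the report times, appending an
#' average-error row. This reproduces the layout of the method-comparison
#' tables: per-time numeric value, true value, and percentage error for
#' both compartments.
#'
#' @param method scheme tag as in [dc_integrate()].
#' @param anchor_state starting [dc_state()] (the default workflow anchors
#'   at the year-five true state of [dc_anchor_fixture()]).
#' @param params a [dc_params()] object.
#' @param dt step size in years.
#' @param report_times times (years) at which to report; must lie on the
#'   step grid. Default `c(5, 10, 15, 20)` intersected with the reachable
#'   grid.
#' @return data.frame of class `dc_error_table` with columns `t`, `C_num`,
#'   `C_true`, `err_C_pct`, `N_num`, `N_true`, `err_N_pct`; the final row
#'   (`t = NA`) holds the column-wise average errors. Attributes `method`
#'   and `dt` carry the run metadata.
#' @export
#' @examples
#' fx <- dc_anchor_fixture()
#' dc_error_table("rk4", fx$anchor, dc_default_params(), dt = 1)
dc_error_table <- function(method, anchor_state, params, dt,
                           report_times = c(5, 10, 15, 20)) {
  report_times <- report_times[report_times >= anchor_state$t]
  if (length(report_times) == 0) stop("no report times at or after the anchor")
  on_grid <- abs((report_times - anchor_state$t) / dt -
                   round((report_times - anchor_state$t) / dt)) < 1e-8
  if (!all(on_grid)) {
    stop("report_times must lie on the step grid", call. = FALSE)
  }
  traj <- dc_integrate(method, anchor_state, params, dt,
                       t_end = max(report_times))
  rows <- lapply(report_times, function(tt) {
    i <- which(abs(traj$t - tt) < 1e-8)[1]
    truth <- dc_propagate(anchor_state, tt - anchor_state$t, params)
    data.frame(t = tt, C_num = traj$C[i], C_true = truth$C,
               err_C_pct = dc_pct_error(traj$C[i], truth$C),
               N_num = traj$N[i], N_true = truth$N,
               err_N_pct = dc_pct_error(traj$N[i], truth$N))
  })
  tab <- do.call(rbind, rows)
  avg <- data.frame(t = NA_real_, C_num = NA_real_, C_true = NA_real_,
                    err_C_pct = mean(tab$err_C_pct),
                    N_num = NA_real_, N_true = NA_real_,
                    err_N_pct = mean(tab$err_N_pct))
  out <- rbind(tab, avg)
  rownames(out) <- NULL
  structure(out, method = method, dt = dt,
            class = c("dc_error_table", "data.frame"))
}

#' Step-size sweep across schemes
#'
#' For every (method, dt) pair: integrates over `[state0$t, t_end]` where
#' the grid allows, records the end-state error on `C` against exact
#' propagation, the divergence flag, and the amplification-based stability
#' verdict of [dc_amplification()].
#'
#' @param methods character vector of scheme tags.
#' @param dts step sizes (years); default a seven-point grid spanning
#'   0.1 to 1.5.
#' @param params a [dc_params()] object.
#' @param state0 initial [dc_state()].
#' @param t_end final time (years).
#' @return data.frame of class `dc_sweep` with one row per (method, dt):
#'   `method`, `dt`, `t_eval`, `err_C_pct`, `diverged`, `amp_stable`,
#'   `spectral_radius`.
#' @export
dc_dt_sweep <- function(methods, dts = c(0.1, 0.25, 0.5, 0.75, 1, 1.25, 1.5),
                        params = dc_default_params(),
                        state0 = dc_initial_state(params), t_end = 20) {
  stopifnot(all(dts > 0))
  grid <- expand.grid(method = methods, dt = dts, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    m <- grid$method[i]; h <- grid$dt[i]
    # largest grid point not beyond t_end
    k <- floor((t_end - state0$t) / h + 1e-9)
    te <- state0$t + k * h
    traj <- dc_integrate(m, state0, params, h, te)
    amp <- dc_amplification(m, params, h)
    last <- traj[nrow(traj), ]
    err <- if (attr(traj, "diverged")) NA_real_ else {
      dc_pct_error(last$C, dc_propagate(state0, te - state0$t, params)$C)
    }
    data.frame(method = m, dt = h, t_eval = last$t, err_C_pct = err,
               diverged = attr(traj, "diverged"),
               amp_stable = amp$stable,
               spectral_radius = amp$spectral_radius)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, axis = "dt", class = c("dc_sweep", "data.frame"))
}

#' One-parameter sweep of equilibrium, spectrum and trajectory
#'
#' For each value of the swept rate: the equilibrium, the eigenvalues, and
#' an RK4 trajectory launched from that parameter set's own equilibrium
#' displaced by +500 persons in each coordinate (so that each trajectory
#' reflects the swept dynamics rather than a foreign initial state).
#'
#' @param param_name one of `"lambda"`, `"delta"`, `"mu"`, `"gamma"`,
#'   `"nu"`, `"incidence"`.
#' @param values non-negative finite values to sweep. A swept `lambda`
#'   above 1 is accepted as a rate (no longer interpretable as a
#'   probability) with a warning.
#' @param base_params the [dc_params()] set supplying the other rates.
#' @param dt,t_end RK4 integration grid (defaults 1 yr over 20 yr).
#' @return data.frame of class `dc_sweep`: per value, `C_star`, `N_star`,
#'   `chi1`, `chi2`, `stability`, end-state `C_end`/`N_end` of the RK4
#'   run, and `err_C_pct` against exact propagation. Trajectories are kept
#'   in the `trajectories` attribute (a named list).
#' @export
dc_param_sweep <- function(param_name, values,
                           base_params = dc_default_params(),
                           dt = 1, t_end = 20) {
  param_name <- match.arg(param_name,
                          c("lambda", "delta", "mu", "gamma", "nu", "incidence"))
  stopifnot(all(is.finite(values)), all(values >= 0))
  if (param_name == "lambda" && any(values > 1)) {
    warning("lambda > 1 is accepted as a rate, not a probability")
  }
  trajs <- list()
  rows <- lapply(values, function(v) {
    pl <- unclass(base_params)
    pl[[param_name]] <- v
    p <- do.call(dc_params, pl)
    eq <- dc_equilibrium(p, "ode_consistent")
    st <- dc_stability(p)
    s0 <- dc_initial_state(p, 500, 500)
    traj <- dc_integrate("rk4", s0, p, dt, t_end)
    trajs[[as.character(v)]] <<- traj
    last <- traj[nrow(traj), ]
    truth <- dc_propagate(s0, last$t - s0$t, p)
    data.frame(value = v, C_star = eq$C_star, N_star = eq$N_star,
               chi1 = Re(st$chi1), chi2 = Re(st$chi2),
               stability = st$stability,
               C_end = last$C, N_end = last$N,
               err_C_pct = if (attr(traj, "diverged")) NA_real_
               else dc_pct_error(last$C, truth$C))
  })
  structure(do.call(rbind, rows), axis = param_name, trajectories = trajs,
            class = c("dc_sweep", "data.frame"))
}

#' Incidence-by-lambda scenario grid
#'
#' Long-run projections of the complications burden over a grid of
#' incidence levels (low/medium/high inflow of new cases) crossed with
#' levels of the complication rate lambda. The default horizon is the
#' equilibrium (infinite horizon); a finite horizon integrates exactly
#' from each scenario's own +500-offset initial state. Because the model
#' is linear in the incidence, every cell scales exactly linearly down an
#' incidence column at the equilibrium horizon.
#'
#' @param I_levels incidence levels (persons/yr); default
#'   `c(2e6, 3e6, 6e6)`.
#' @param lambda_levels complication-rate levels; default
#'   `c(0.3, 0.4, 0.5)`.
#' @param base_params the [dc_params()] set supplying the other rates.
#' @param horizon `Inf` (default) for the equilibrium, or a finite time in
#'   years.
#' @return data.frame of class `dc_scenario_grid` with columns `incidence`,
#'   `lambda`, `C`, `N`.
#' @export
dc_incidence_grid <- function(I_levels = c(2e6, 3e6, 6e6),
                              lambda_levels = c(0.3, 0.4, 0.5),
                              base_params = dc_default_params(),
                              horizon = Inf) {
  grid <- expand.grid(incidence = I_levels, lambda = lambda_levels)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pl <- unclass(base_params)
    pl$incidence <- grid$incidence[i]
    pl$lambda <- grid$lambda[i]
    p <- do.call(dc_params, pl)
    if (pl$incidence == 0) {
      cn <- c(0, 0)  # homogeneous system: equilibrium at the origin
    } else if (is.infinite(horizon)) {
      eq <- dc_equilibrium(p, "ode_consistent")
      cn <- c(eq$C_star, eq$N_star)
    } else {
      s <- dc_propagate(dc_initial_state(p, 500, 500), horizon, p)
      cn <- c(s$C, s$N)
    }
    data.frame(incidence = grid$incidence[i], lambda = grid$lambda[i],
               C = cn[1], N = cn[2])
  })
  structure(do.call(rbind, rows), horizon = horizon,
            class = c("dc_scenario_grid", "data.frame"))
}
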