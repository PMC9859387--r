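steppers <- list(
  explicit_euler = dc_step_explicit_euler,
  implicit_euler = dc_step_implicit_euler,
  heun = dc_step_heun,
  rk4 = dc_step_rk4)

test_that("every scheme holds the equilibrium fixed for 100 steps", {
  p <- default_p
  eq <- dc_equilibrium(p)
  for (m in c(names(steppers), "abm4", "analytic")) {
    traj <- dc_integrate(m, dc_state(0, eq$C_star, eq$N_star), p, 1, 100)
    expect_lt(max(rel_err(traj$C, eq$C_star)), 1e-12, label = m)
    expect_lt(max(rel_err(traj$N, eq$N_star)), 1e-12, label = m)
    expect_false(attr(traj, "diverged"))
  }
})

test_that("explicit Euler is consistent: one step equals state plus dt times rhs", {
  p <- default_p
  s <- anchor_fx$anchor
  r <- dc_rhs(s, p)
  out <- dc_step_explicit_euler(s, 1, p)
  expect_equal(out$C, s$C + r[["dC"]], tolerance = 1e-14)
  expect_equal(out$N, s$N + r[["dN"]], tolerance = 1e-14)
  # near the printed trajectory C falls by ~5.3e4 persons in a year
  expect_lt(out$C - s$C, -5e4)
  expect_gt(out$C - s$C, -6e4)
  # dt -> 0 limit recovers the derivative for all schemes
  for (st in steppers) {
    o <- st(s, 1e-7, p)
    expect_equal((o$C - s$C) / 1e-7, r[["dC"]], tolerance = 1e-5)
  }
})

test_that("backward Euler solves the coupled pair exactly", {
  p <- default_p
  s <- anchor_fx$anchor
  out <- dc_step_implicit_euler(s, 1, p)
  # residual of the implicit equations at the returned state must vanish
  r <- dc_rhs(out, p)
  expect_lt(rel_err(out$C, s$C + 1 * r[["dC"]]), 1e-12)
  expect_lt(rel_err(out$N, s$N + 1 * r[["dN"]]), 1e-12)

  # fixed-point iteration oracle on the sequentially written update pair
  theta <- 0.62
  Cn <- s$C; Nn <- s$N
  for (i in 1:200) {
    Cn <- (1 * (p$incidence + p$lambda * Nn) + s$C) / (1 + 1 * (p$lambda + theta))
    Nn <- (1 * (2 * p$incidence - Cn * (p$nu + p$delta)) + s$N) / (1 + 1 * p$mu)
  }
  expect_lt(rel_err(out$C, Cn), 1e-10)
  expect_lt(rel_err(out$N, Nn), 1e-10)

  # decoupled scalar reduction: C_{i+1} = C_i / (1 + dt*theta)
  pd <- dc_params(0, 0, 0.3, 0.5, 0, 0)
  sd <- dc_state(0, 100, 300)
  od <- dc_step_implicit_euler(sd, 2, pd)
  expect_equal(od$C, 100 / (1 + 2 * 0.8), tolerance = 1e-14)
  expect_equal(od$N, 300 / (1 + 2 * 0.3), tolerance = 1e-14)

  # the one-sweep sequential variant differs from the exact solve but
  # agrees in the dt -> 0 limit
  gs <- dc_step_implicit_euler(s, 1, p, gauss_seidel = TRUE)
  expect_false(isTRUE(all.equal(gs$C, out$C)))
  gs_small <- dc_step_implicit_euler(s, 1e-6, p, gauss_seidel = TRUE)
  ex_small <- dc_step_implicit_euler(s, 1e-6, p)
  expect_lt(rel_err(gs_small$C, ex_small$C), 1e-9)
})

test_that("Heun's step equals the two-stage arithmetic oracle", {
  p <- default_p
  s <- anchor_fx$anchor
  theta <- 0.62
  f <- function(C, N) c(6e6 - (0.85 + theta) * C + 0.85 * N,
                        12e6 - 0.1 * C - 0.02 * N)
  f0 <- f(s$C, s$N)
  pred <- c(s$C, s$N) + 1 * f0
  f1 <- f(pred[1], pred[2])
  expected <- c(s$C, s$N) + 0.5 * (f0 + f1)
  out <- dc_step_heun(s, 1, p)
  expect_equal(c(out$C, out$N), expected, tolerance = 1e-14)
})

test_that("scalar reductions recover the schemes' stability polynomials", {
  # lambda = 0 and I = 0 decouple C as pure decay C' = -theta C
  pd <- dc_params(0, 0.1, 0.1, 0.2, 0.1, 0)
  theta <- 0.5
  s <- dc_state(0, 1000, 0)
  for (dt in c(0.4, 1, 2)) {
    x <- theta * dt
    expect_equal(dc_step_heun(s, dt, pd)$C / 1000, 1 - x + x^2 / 2,
                 tolerance = 1e-12)
    expect_equal(dc_step_rk4(s, dt, pd)$C / 1000,
                 1 - x + x^2 / 2 - x^3 / 6 + x^4 / 24, tolerance = 1e-12)
    expect_equal(dc_step_explicit_euler(s, dt, pd)$C / 1000, 1 - x,
                 tolerance = 1e-12)
  }
})

test_that("RK4 at a one-year step tracks the exact propagator to sub-person error", {
  p <- default_p
  s <- anchor_fx$anchor
  traj <- dc_integrate("rk4", s, p, 1, 20)
  truth <- dc_propagate(s, 15, p)
  expect_lt(abs(traj$C[nrow(traj)] - truth$C), 0.15)
})

test_that("the multistep scheme needs four equispaced states and is then 4th order accurate", {
  p <- default_p
  s <- anchor_fx$anchor
  expect_error(dc_step_abm4(list(s, s), 1, p),
               class = "dcmodel_insufficient_history")
  bad <- list(dc_state(0, 1, 2), dc_state(1, 1, 2), dc_state(2.5, 1, 2),
              dc_state(3, 1, 2))
  expect_error(dc_step_abm4(bad, 1, p),
               class = "dcmodel_insufficient_history")

  # constant (equilibrium) history: all derivatives vanish
  eq <- dc_equilibrium(p)
  hist <- lapply(0:3, function(k) dc_state(k, eq$C_star, eq$N_star))
  out <- dc_step_abm4(hist, 1, p)
  expect_equal(out$C, eq$C_star, tolerance = 1e-14)

  # full run against the exact propagator from a seeded stable state
  for (p2 in dc_random_params(19, 3)) {
    s0 <- dc_initial_state(p2, 500, 500)
    traj <- dc_integrate("abm4", s0, p2, 0.5, 20)
    truth <- dc_propagate(s0, 20, p2)
    expect_lt(rel_err(traj$C[nrow(traj)], truth$C), 1e-6)
  }
})

test_that("integration grid, analytic delegation and divergence guard behave", {
  p <- default_p
  s <- anchor_fx$anchor
  single <- dc_integrate("rk4", s, p, 1, s$t)
  expect_equal(nrow(single), 1L)
  expect_equal(single$C, s$C)
  expect_error(dc_integrate("rk4", s, p, 1, s$t + 2.5), "grid")

  tr_a <- dc_integrate("analytic", s, p, 1, 10)
  pr <- dc_propagate(s, 5, p)
  expect_lt(rel_err(tr_a$C[6], pr$C), 1e-12)
  expect_equal(diff(tr_a$t), rep(1, 5), tolerance = 1e-12)

  # forward Euler beyond its stability limit grows without bound
  div <- dc_integrate("explicit_euler", s, p, 1.6, s$t + 1.6 * 600)
  expect_true(attr(div, "diverged"))
  expect_true(is.finite(attr(div, "t_diverged")))
  expect_lt(nrow(div), 601)
})

test_that("empirical convergence orders match the schemes' theoretical orders", {
  p <- default_p
  s <- anchor_fx$anchor
  truth <- dc_propagate(s, 15, p)$C
  err_at <- function(m, dt) {
    tr <- dc_integrate(m, s, p, dt, 20)
    abs(tr$C[nrow(tr)] - truth)
  }
  orders <- c(explicit_euler = 1, implicit_euler = 1, heun = 2, rk4 = 4,
              abm4 = 4)
  tols <- c(explicit_euler = 0.1, implicit_euler = 0.1, heun = 0.1,
            rk4 = 0.3, abm4 = 0.5)
  # the multistep scheme is measured one halving later: at a one-year step
  # its start-up transient (fast mode at dt*eta2 = 1.4) still dominates
  base_dt <- c(explicit_euler = 1, implicit_euler = 1, heun = 1, rk4 = 1,
               abm4 = 0.5)
  for (m in names(orders)) {
    obs <- log2(err_at(m, base_dt[[m]]) / err_at(m, base_dt[[m]] / 2))
    expect_lt(abs(obs - orders[[m]]), tols[[m]],
              label = sprintf("%s order %.3f", m, obs))
  }
})

test_that("error ranking at a one-year step and improvement under halving hold", {
  p <- default_p
  s <- anchor_fx$anchor
  truth <- dc_propagate(s, 15, p)$C
  errs <- vapply(c("rk4", "abm4", "heun", "implicit_euler", "explicit_euler"),
                 function(m) {
                   tr <- dc_integrate(m, s, p, 1, 20)
                   abs(tr$C[nrow(tr)] - truth)
                 }, numeric(1))
  expect_true(all(diff(errs) > 0))  # rk4 < abm4 < heun < implicit < explicit
  for (m in names(errs)) {
    tr_h <- dc_integrate(m, s, p, 0.5, 20)
    expect_lt(abs(tr_h$C[nrow(tr_h)] - truth), errs[[m]])
  }
})

test_that("trajectories scale linearly with the problem", {
  p <- default_p
  k <- 3.5
  pk <- dc_params(p$lambda, p$delta, p$mu, p$gamma, p$nu, k * p$incidence)
  s <- anchor_fx$anchor
  sk <- dc_state(s$t, k * s$C, k * s$N)
  for (m in c("explicit_euler", "implicit_euler", "heun", "rk4", "abm4")) {
    tr <- dc_integrate(m, s, p, 1, 12)
    trk <- dc_integrate(m, sk, pk, 1, 12)
    expect_lt(max(rel_err(trk$C, k * tr$C)), 1e-12, label = m)
    expect_lt(max(rel_err(trk$N, k * tr$N)), 1e-12, label = m)
  }
})

test_that("amplification factors match theory and simulation", {
  p <- default_p
  d <- dc_derived(p)
  # forward Euler: stable iff dt <= 2/eta2
  lim <- 2 / d$eta2
  expect_true(dc_amplification("explicit_euler", p, lim * 0.99)$stable)
  expect_false(dc_amplification("explicit_euler", p, lim * 1.01)$stable)
  expect_equal(unname(dc_amplification("explicit_euler", p, 1.5)$factors[2]),
               1 - 1.5 * d$eta2, tolerance = 1e-12)

  # backward Euler: factors in (0,1) for any positive step
  for (dt in c(0.1, 1, 10, 100)) {
    a <- dc_amplification("implicit_euler", p, dt)
    expect_true(all(a$factors > 0 & a$factors < 1))
    expect_true(a$stable)
  }

  # dt -> 0: every scheme's factors tend to 1
  for (m in c("explicit_euler", "implicit_euler", "heun", "rk4", "abm4",
              "analytic")) {
    a <- dc_amplification(m, p, 1e-8)
    expect_equal(unname(a$factors), c(1, 1), tolerance = 1e-6, label = m)
  }

  # analytic factors are exactly the modal decay
  a <- dc_amplification("analytic", p, 0.7)
  expect_equal(unname(a$factors), exp(-0.7 * c(d$eta1, d$eta2)),
               tolerance = 1e-14)

  # multistep root against a direct simulation of the scalar PECE
  # recurrence (x small enough that the dominant root is real, so the
  # one-step ratio converges to it)
  x <- 0.5  # dt*eta
  y <- exp(-x * (0:3))  # exact start-up values
  for (i in 1:300) {
    n <- length(y)
    pr <- y[n] + (x / 24) * -(55 * y[n] - 59 * y[n - 1] + 37 * y[n - 2] -
                                9 * y[n - 3])
    yn <- y[n] + (x / 24) * (9 * -pr + 19 * -y[n] - 5 * -y[n - 1] +
                               -y[n - 2])
    y <- c(y, yn)
  }
  sim_ratio <- abs(y[304] / y[303])
  pd <- dc_params(0, 0.1, 0.1, 0.2, 0.1, 0)  # theta = 0.5 scalar decay
  amp <- dc_amplification("abm4", pd, x / 0.5)
  expect_equal(unname(amp$factors[2]), sim_ratio, tolerance = 1e-6)
  # and the multistep scheme loses stability between x = 1.2 and 1.3,
  # i.e. a step of ~2.5 yr for the pure-decay test problem
  expect_true(dc_amplification("abm4", pd, 1.2 / 0.5)$stable)
  expect_false(dc_amplification("abm4", pd, 1.3 / 0.5)$stable)
})
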