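# shared fixtures for the suite
default_p <- dc_default_params()
anchor_fx <- dc_anchor_fixture()

# relative-difference helper
rel_err <- function(x, y) abs(x - y) / pmax(abs(y), .Machine$double.eps)

# independent brute-force truth: very fine RK4 re-implemented inline
# (kept separate from the package steppers on purpose)
fine_rk4_truth <- function(state, params, t_total, h = 0.01) {
  theta <- params$gamma + params$mu + params$nu + params$delta
  f <- function(x) c(params$incidence - (params$lambda + theta) * x[1] +
                       params$lambda * x[2],
                     2 * params$incidence -
                       (params$nu + params$delta) * x[1] - params$mu * x[2])
  x <- c(state$C, state$N)
  n <- round(t_total / h)
  for (i in seq_len(n)) {
    k1 <- f(x); k2 <- f(x + h / 2 * k1); k3 <- f(x + h / 2 * k2)
    k4 <- f(x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}
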