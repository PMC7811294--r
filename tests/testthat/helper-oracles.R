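# Independent fixed-step explicit-Euler oracle.  The right-hand sides are
# written out here directly from the model equations, independently of the
# package's implementation, so solver and formulation are both cross-checked.

oracle_rhs_mono <- function(y, p) {
  A <- y[1]; W <- y[2]; R <- y[3]; X <- y[4]
  growth2 <- if (p[["r2"]] > 0) p[["r2"]] * R / (p[["K2"]] + R) else 0
  c(-p[["k1"]] * A * X + p[["c2"]] * p[["k2"]] * W * R * X,
    p[["c1"]] * p[["k1"]] * A * X - p[["k2"]] * W * R * X + p[["h"]] * X,
    -p[["k2"]] * W * R * X - p[["k3"]] * R * X,
    (p[["r1"]] * A / (p[["K1"]] + A) + growth2 - p[["d1"]] * W - p[["d2"]]) * X)
}

oracle_rhs_co <- function(y, pf, pc, g, m) {
  A <- y[1]; W <- y[2]; R <- y[3]; X <- y[4]; Y <- y[5]; L <- y[6]
  gr2f <- if (pf[["r2"]] > 0) pf[["r2"]] * R / (pf[["K2"]] + R) else 0
  gr2c <- if (pc[["r2"]] > 0) pc[["r2"]] * R / (pc[["K2"]] + R) else 0
  c(-pf[["k1"]] * A * X + pf[["c2"]] * pf[["k2"]] * W * R * X -
      pc[["k1"]] * A * Y + pc[["c2"]] * pc[["k2"]] * W * R * Y,
    pf[["c1"]] * pf[["k1"]] * A * X - pf[["k2"]] * W * R * X +
      pc[["c1"]] * pc[["k1"]] * A * Y - pc[["k2"]] * W * R * Y +
      pf[["h"]] * X + pc[["h"]] * Y,
    -pf[["k2"]] * W * R * X - pc[["k2"]] * W * R * Y -
      pf[["k3"]] * R * X - pc[["k3"]] * R * Y,
    (pf[["r1"]] * A / (pf[["K1"]] + A) + gr2f - pf[["d1"]] * W - pf[["d2"]] -
       m * L^2) * X,
    (pc[["r1"]] * A / (pc[["K1"]] + A) + gr2c - pc[["d1"]] * W - pc[["d2"]] -
       m * L^2) * Y,
    g * X * Y)
}

# fixed-step explicit Euler sampled at out_times (which must be multiples
# of dt); rhs_fn(y) returns the derivative
euler_integrate <- function(y0, out_times, dt, rhs_fn) {
  t_end <- max(out_times)
  n_steps <- round(t_end / dt)
  out <- matrix(NA_real_, length(out_times), length(y0))
  out_idx <- round(out_times / dt)
  y <- y0
  k <- 1L
  for (s in 0:n_steps) {
    if (k <= length(out_idx) && s == out_idx[k]) {
      out[k, ] <- y
      k <- k + 1L
    }
    if (s < n_steps) y <- y + dt * rhs_fn(y)
  }
  out
}

euler_mono <- function(p, y0, out_times, dt = 1e-3) {
  euler_integrate(y0, out_times, dt, function(y) oracle_rhs_mono(y, p))
}

euler_co <- function(pf, pc, g, m, y0, out_times, dt = 1e-3) {
  euler_integrate(y0, out_times, dt,
                  function(y) oracle_rhs_co(y, pf, pc, g, m))
}

# mixed relative/absolute agreement used against the Euler oracle
# (components below `floor` are compared on the absolute scale rel * floor)
expect_rel_close <- function(got, want, rel = 1e-3, floor = 1e-6) {
  err <- abs(got - want) / pmax(abs(want), floor)
  expect_lt(max(err), rel)
}
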