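# Shared oracles and toy systems for the tests.

# componentwise central finite-difference Jacobian of f
fd_jacobian <- function(f, y, eps = 1e-6) {
  d <- length(y)
  J <- matrix(NA_real_, d, d)
  for (j in seq_len(d)) {
    e <- numeric(d); e[j] <- eps
    J[, j] <- (f(y + e) - f(y - e)) / (2 * eps)
  }
  J
}

# directional finite difference of f along f: oracle for g = f'(y) f(y)
fd_g <- function(f, y, eps = 1e-6) {
  fy <- f(y)
  (f(y + eps * fy) - f(y - eps * fy)) / (2 * eps)
}

# scalar linear test problem y' = lambda y, g = lambda^2 y (R stepping path)
scalar_linear_system <- function(lambda) {
  eftdrk:::.new_ode_system(
    "scalar_linear", 1L,
    f = function(y) lambda * y,
    jac = function(y) matrix(lambda, 1, 1),
    state_names = "y", params = list(lambda = lambda))
}

# harmonic oscillator / linear center y1' = w0 y2, y2' = -w0 y1
linear_center_system <- function(w0) {
  J <- matrix(c(0, w0, -w0, 0), 2, 2, byrow = TRUE)
  eftdrk:::.new_ode_system(
    "linear_center", 2L,
    f = function(y) as.vector(J %*% y),
    jac = function(y) J,
    state_names = c("y1", "y2"), params = list(w0 = w0))
}

# log-log slope of err(h)
loglog_slope <- function(h, err) {
  unname(stats::coef(stats::lm(log(err) ~ log(h)))[2])
}
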