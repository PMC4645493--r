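# Stage structure and frequency-dependent weights.

test_that("the limit tableau carries the expected stage structure", {
  tab <- limit_tableau()
  expect_equal(tab$c, c(0, 1 / 4, 2 / 3, 1))
  expect_equal(tab$A[2, 1], 1 / 32)
  expect_equal(tab$A[3, 1:2], c(-2 / 81, 20 / 81))
  expect_equal(tab$A[4, 1:3], c(5 / 4, -6 / 5, 9 / 20))
  expect_true(all(tab$A[upper.tri(tab$A, diag = TRUE)] == 0))
  # row sums equal c_i^2 / 2 (the constructor also asserts this exactly)
  expect_equal(rowSums(tab$A), tab$c^2 / 2)
  expect_equal(sum(tab$b_limit), 1 / 2)
  expect_equal(sum(tab$b_limit * tab$c), 1 / 6)
  expect_equal(sum(tab$b_limit * tab$c^2), 1 / 12)
})

test_that("weights at nu = 0 reduce exactly to the prototype", {
  tab <- limit_tableau()
  for (m in c("prototype", "a", "b", "c")) {
    w <- fitted_weights(m, 0)
    expect_identical(w$eta, 1)
    expect_identical(w$beta, 1)
    expect_identical(unname(w$b), tab$b_limit)
  }
  expect_equal(weights_series("b", 0)$b[2], 64 / 225)
})

test_that("weights are even functions of nu", {
  for (m in c("a", "b", "c")) {
    wp <- weights_series(m, 0.3)
    wm <- weights_series(m, -0.3)
    expect_identical(c(wp$eta, wp$beta, wp$b), c(wm$eta, wm$beta, wm$b),
                     label = paste("method", m))
  }
  wa <- weights_a(0.7); wb <- weights_a(-0.7)
  expect_equal(c(wa$eta, wa$beta, wa$b), c(wb$eta, wb$beta, wb$b),
               tolerance = 1e-12)
})

test_that("the exact solve agrees with the printed series for method a", {
  # at the switch point both branches agree to >= 10 significant digits
  x <- eftdrk:::.solve_weights_a_cpp(0.05)
  w <- weights_series("a", 0.05)
  rel <- abs(x - c(w$eta, w$beta, w$b)) / abs(c(w$eta, w$beta, w$b))
  expect_lt(max(rel), 1e-10)
  # across [0.05, 0.5] the difference shrinks like the nu^10 series tail
  nus <- c(0.05, 0.1, 0.2, 0.3, 0.5)
  diffs <- vapply(nus, function(nu) {
    x <- eftdrk:::.solve_weights_a_cpp(nu)
    w <- weights_series("a", nu)
    max(abs(x - c(w$eta, w$beta, w$b)))
  }, numeric(1))
  expect_true(all(diffs <= 1e-6 * nus^10 + 1e-13))
  # branch bookkeeping
  expect_identical(weights_a(0.01)$source, "series")
  expect_identical(weights_a(0.5)$source, "exact_solve")
})

test_that("the solved weights satisfy all six fitting equations", {
  for (nu in c(0.2, 1.0, 2.0)) {
    w <- weights_a(nu)
    sys <- eftdrk:::.weights_a_system(nu)
    resid <- max(abs(sys$M %*% c(w$eta, w$beta, w$b) - sys$rhs))
    expect_lt(resid, 1e-12)
  }
})

test_that("eta - 1 and beta - 1 vanish at their certified orders", {
  nus <- 10^seq(-1, -3, by = -0.5)
  for (m in c("a", "b", "c")) {
    cs <- coefficient_series(m)
    # evaluate the constant-free tails directly: the deviations sit far
    # below double rounding of values near 1
    one <- power_series(1, order = 10)
    eta_dev <- abs(ps_eval(series_arith("sub", cs$eta, one), nus))
    beta_dev <- abs(ps_eval(series_arith("sub", cs$beta, one), nus))
    expect_gt(loglog_slope(nus, eta_dev), 6.5)
    expect_gt(loglog_slope(nus, beta_dev), 5.5)
  }
})

test_that("method c weights equal method a weights at twice the frequency", {
  # consequence of fitting t exp(2 i omega t) instead of t exp(i omega t);
  # holds exactly for the printed series coefficients
  for (nu in c(0.1, 0.4, 0.7)) {
    wc <- weights_series("c", nu)
    wa <- weights_series("a", 2 * nu)
    expect_identical(c(wc$eta, wc$beta, wc$b), c(wa$eta, wa$beta, wa$b))
  }
})

test_that("leaving the series validity radius records a warning", {
  expect_warning(weights_series("b", 1.8), "validity radius")
  expect_silent(weights_series("b", 1.2))
})
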