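# Fixed-step TDRK and RK6 stepping: exactness, order, accounting.

test_that("a steady state is a fixed point of the prototype step", {
  sys <- two_gene_system()
  y_star <- unname(find_steady_state(sys, rep(0.5, 4))$y_star)
  y1 <- tdrk_step(sys, y_star, 0.25)
  expect_lt(max(abs(y1 - y_star)), 1e-13)
})

test_that("one prototype step on y' = lambda y is seventh-order accurate", {
  lam <- -2
  sys <- scalar_linear_system(lam)
  # h range chosen so the h^7 local error stays well above double rounding
  hs <- 10^seq(-0.5, -1.25, by = -0.25)
  errs <- vapply(hs, function(h)
    abs(tdrk_step(sys, 1, h) - exp(lam * h)), numeric(1))
  expect_gt(loglog_slope(hs, errs), 6.5)
})

test_that("one coarse TDRK step matches a composed fine-step reference", {
  sys <- two_gene_system()
  y0 <- c(0.6, 0.8, 0.4, 0.6)
  coarse <- tdrk_step(sys, y0, 1 / 4)
  fine <- integrate_fixed(sys, y0, 0, 1 / 4, 1 / 1024)$states
  expect_lt(max(abs(coarse - fine[nrow(fine), ])), 1e-6)
})

test_that("the RK6 baseline tableau is consistent and sixth order", {
  tab <- rk6_baseline_tableau()
  expect_equal(sum(tab$b), 1)
  expect_equal(rowSums(tab$A), tab$c)
  # classical quadrature-order conditions up to order 6
  expect_equal(sum(tab$b * tab$c), 1 / 2)
  expect_equal(sum(tab$b * tab$c^2), 1 / 3)
  expect_equal(sum(tab$b * tab$c^5), 1 / 6)
  lam <- -1.3
  sys <- scalar_linear_system(lam)
  hs <- 10^seq(-0.3, -1, by = -0.175)
  errs <- vapply(hs, function(h) {
    tr <- integrate_fixed(sys, 1, 0, h, h, method = "rk6")
    abs(tr$states[2, 1] - exp(lam * h))
  }, numeric(1))
  expect_gt(loglog_slope(hs, errs), 6.5)
})

test_that("RK6 conserves harmonic-oscillator energy to 1e-10 over 1000 steps", {
  sys <- linear_center_system(1)
  tr <- integrate_fixed(sys, c(1, 0), 0, 10, 0.01, method = "rk6")
  energy <- rowSums(tr$states^2)
  expect_lt(max(abs(energy - 1)), 1e-10)
  expect_identical(tr$eval_counts$n_f, 7L * 1000L)
})

test_that("evaluation accounting is exact", {
  sys <- two_gene_system()
  tr <- integrate_fixed(sys, c(0.6, 0.8, 0.4, 0.6), 0, 100, 1 / 4)
  expect_identical(tr$eval_counts$n_f, 400L)
  expect_identical(tr$eval_counts$n_g, 1600L)
  # the R stepping path counts the same way
  rsys <- sys; rsys$compiled_id <- NA_integer_
  tr2 <- integrate_fixed(rsys, c(0.6, 0.8, 0.4, 0.6), 0, 10, 1 / 4)
  expect_identical(tr2$eval_counts$n_f, 40L)
  expect_identical(tr2$eval_counts$n_g, 160L)
})

test_that("a zero-length interval returns the initial state with no work", {
  sys <- two_gene_system()
  tr <- integrate_fixed(sys, c(0.6, 0.8, 0.4, 0.6), 5, 5, 1 / 4)
  expect_identical(nrow(tr$states), 1L)
  expect_equal(unname(tr$states[1, ]), c(0.6, 0.8, 0.4, 0.6))
  expect_identical(tr$eval_counts$n_f, 0L)
})

test_that("a step that does not divide the interval is rejected", {
  sys <- two_gene_system()
  expect_error(integrate_fixed(sys, c(0.6, 0.8, 0.4, 0.6), 0, 1, 0.3),
               "does not divide")
})

test_that("fitted methods at omega = 0 are bit-identical to the prototype", {
  sys <- per_circadian_system()
  y0 <- c(0.1, 0.25, 0.25, 0.25, 0.25)
  base <- integrate_fixed(sys, y0, 0, 100, 1 / 2, "prototype")
  for (m in c("efa", "efb", "efc")) {
    tr <- integrate_fixed(sys, y0, 0, 100, 1 / 2, m, omega = 0)
    expect_identical(tr$states, base$states, label = m)
  }
})

test_that("compiled and R stepping paths agree", {
  for (sys in list(two_gene_system(), per_circadian_system())) {
    rsys <- sys; rsys$compiled_id <- NA_integer_
    y0 <- if (sys$dim == 4) c(0.6, 0.8, 0.4, 0.6) else
      c(0.1, 0.25, 0.25, 0.25, 0.25)
    a <- integrate_fixed(sys, y0, 0, 2, 0.1, "efa", omega = 1.5)
    b <- integrate_fixed(rsys, y0, 0, 2, 0.1, "efa", omega = 1.5)
    expect_lt(max(abs(a$states - b$states)), 1e-13)
    a6 <- integrate_fixed(sys, y0, 0, 2, 0.1, "rk6")
    b6 <- integrate_fixed(rsys, y0, 0, 2, 0.1, "rk6")
    expect_lt(max(abs(a6$states - b6$states)), 1e-13)
  }
})

test_that("overflow is reported as a step failure with its time", {
  sys <- scalar_linear_system(1)
  expect_error(integrate_fixed(sys, 1, 0, 2000, 5),
               "integration failed at t = ")
})

test_that("trajectories serialise to CSV with a JSON sidecar", {
  sys <- two_gene_system()
  tr <- integrate_fixed(sys, c(0.6, 0.8, 0.4, 0.6), 0, 1, 1 / 4)
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  df <- utils::read.csv(f)
  expect_identical(names(df), c("time", "m1", "m2", "p1", "p2"))
  expect_identical(nrow(df), 5L)
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_identical(meta$n_f, 4L)
  unlink(c(f, paste0(f, ".json")))
})
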