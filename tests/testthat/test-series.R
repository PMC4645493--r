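# Exact rational power-series arithmetic and the order-condition checker.

test_that("series arithmetic is exact and tracks truncation", {
  p1 <- power_series(c(1, 1))           # 1 + nu
  p2 <- power_series(c(1, -1))          # 1 - nu
  prod <- series_arith("mul", p1, p2)
  expect_true(ps_coef_is(prod, 0, 1))
  expect_true(ps_coef_is(prod, 1, 0))
  expect_equal(prod$order, 1L)          # min of the input orders

  lo <- power_series(c(1, 0, 2), order = 4)
  hi <- power_series(c(3, 1), order = 8)
  expect_equal(series_arith("mul", lo, hi)$order, 4L)
  expect_equal(series_arith("add", lo, hi)$order, 4L)

  third <- series_arith("scale", power_series(c(1, 1, 1)), c(1, 3))
  expect_true(ps_coef_is(third, 2, 1, 3))

  # big-denominator coefficients survive arithmetic exactly
  big <- power_series(list(1), list("86770994223513600000"), order = 0)
  twice <- series_arith("add", big, big)
  expect_true(ps_coef_is(twice, 0, 1, "43385497111756800000"))
})

test_that("weight series have the printed exact coefficients", {
  cs_a <- coefficient_series("a")
  expect_true(ps_coef_is(cs_a$b[[1]], 0, 3, 40))
  expect_true(ps_coef_is(cs_a$b[[1]], 2, 1, 11200))
  expect_true(ps_coef_is(cs_a$b[[2]], 0, 64, 225))
  expect_true(ps_coef_is(cs_a$eta, 8, 23, 348364800))
  cs_b <- coefficient_series("b")
  expect_true(ps_coef_is(cs_b$beta, 6, 1, 189000))
  expect_true(ps_coef_is(cs_b$b[[3]], 0, 27, 200))
  cs_c <- coefficient_series("c")
  expect_true(ps_coef_is(cs_c$b[[1]], 2, 1, 2800))
  expect_true(ps_coef_is(cs_c$b[[1]], 4, -4601, 54432000))
  # constant terms of every series equal the limit weights
  tab <- limit_tableau()
  for (m in c("a", "b", "c")) {
    cs <- coefficient_series(m)
    expect_true(ps_coef_is(cs$eta, 0, 1))
    expect_true(ps_coef_is(cs$beta, 0, 1))
    for (i in 1:4)
      expect_true(ps_coef_is(cs$b[[i]], 0, tab$b_exact[[i]][1],
                             tab$b_exact[[i]][2]),
                  label = sprintf("method %s b%d constant", m, i))
  }
})

test_that("the four b_i series sum to 1/2 with vanishing nu^2 and nu^4 terms", {
  for (m in c("a", "b", "c")) {
    cs <- coefficient_series(m)
    s <- cs$b[[1]]
    for (i in 2:4) s <- series_arith("add", s, cs$b[[i]])
    expect_true(ps_coef_is(s, 0, 1, 2), label = paste("method", m))
    expect_true(ps_coef_is(s, 2, 0), label = paste("method", m))
    expect_true(ps_coef_is(s, 4, 0), label = paste("method", m))
  }
})

test_that("all order conditions pass for each method, in exact arithmetic", {
  tab <- limit_tableau()
  for (m in c("a", "b", "c")) {
    rep <- check_order_conditions(coefficient_series(m), tab)
    expect_true(all(rep$checkable), label = paste("method", m))
    expect_true(attr(rep, "all_pass"), label = paste("method", m))
    # pre-simplification list with A e computed from the stage matrix
    full <- check_order_conditions(coefficient_series(m), tab, full = TRUE)
    expect_equal(nrow(full), 15L)
    expect_true(attr(full, "all_pass"), label = paste("method", m, "full"))
  }
})

test_that("an injected coefficient fault is caught at the exact power", {
  cs <- coefficient_series("a")
  # perturb the constant term of b1 by 1e-6 (exactly, as a rational)
  cs$b[[1]] <- series_arith("add", cs$b[[1]],
                            power_series(c(1), c(1000000), order = 8))
  rep <- check_order_conditions(cs)
  be <- rep[rep$condition == "b.e = 1/2 + O(nu^5)", ]
  expect_false(be$passed)
  expect_identical(be$first_offending_power, 0L)
})

test_that("insufficient truncation is reported, never silently passed", {
  cs <- coefficient_series("a")
  cs$eta <- power_series(c(1), order = 3)  # valid only to nu^3 < required 6
  rep <- check_order_conditions(cs)
  eta_row <- rep[rep$condition == "eta = 1 + O(nu^7)", ]
  expect_false(eta_row$checkable)
  expect_true(eta_row$passed)  # nothing checkable failed
  expect_true(is.logical(attr(rep, "all_pass")))
})
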