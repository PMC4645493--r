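# Model vector fields, analytic Jacobians and g = J f.

test_that("Hill functions satisfy their defining identities", {
  expect_equal(hill("activation", 0.21, 0.21, 3), 1 / 2)
  expect_equal(hill("inhibition", 0.21, 0.21, 3), 1 / 2)
  p <- c(0, 0.05, 0.3, 1, 10)
  expect_equal(hill("activation", p, 0.4, 2.5) +
                 hill("inhibition", p, 0.4, 2.5), rep(1, length(p)))
  expect_identical(hill("activation", 0, 0.4, 2.5), 0)
  # inhibition is monotone decreasing with limit 0
  vals <- hill("inhibition", c(1, 10, 100, 1e6), 0.4, 3)
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[4], 1e-18)
  expect_error(hill("activation", -0.1, 0.4, 2), "negative")
})

test_that("parameter constructors validate positivity", {
  expect_error(two_gene_params(lambda1 = -1), "lambda1")
  expect_error(per_params(vs = 0), "vs")
})

test_that("the two-gene vector field vanishes at the published steady state", {
  sys <- two_gene_system()
  y_star <- c(0.475099, 0.186810, 0.475099, 0.186810)
  expect_true(all(abs(sys$f(y_star)) < 5e-6))
})

test_that("the PER vector field vanishes at the published steady state", {
  sys <- per_circadian_system()
  y_star <- c(1.851476, 1.049558, 0.672924, 0.570982, 0.834512)
  expect_true(all(abs(sys$f(y_star)) < 5e-6))
})

test_that("analytic Jacobians and g pass finite-difference oracles", {
  set.seed(42)
  for (sys in list(two_gene_system(), per_circadian_system())) {
    for (k in 1:50) {
      y <- stats::runif(sys$dim, 0.05, 2)
      expect_lt(max(abs(sys$jac(y) - fd_jacobian(sys$f, y))), 1e-7,
                label = sprintf("%s jac at draw %d", sys$name, k))
      gy <- sys$g(y)
      expect_lt(max(abs(gy - fd_g(sys$f, y))), 1e-7 * max(1, max(abs(gy))),
                label = sprintf("%s g at draw %d", sys$name, k))
    }
  }
})

test_that("two-gene g matches the closed-form expression", {
  # independently transcribed closed form of J f for the cross-regulation
  # model, used only as an oracle
  p <- two_gene_params()
  g_closed <- function(y) {
    m1 <- y[1]; m2 <- y[2]; p1 <- y[3]; p2 <- y[4]
    d1 <- p$theta1^p$n1 + p1^p$n1
    d2 <- p$theta2^p$n2 + p2^p$n2
    Hp <- p2^p$n2 / d2
    Hm <- p$theta1^p$n1 / d1
    c(p$gamma1 * (p$gamma1 * m1 - p$lambda1 * Hp) +
        p$lambda1 * p$n2 * p$theta2^p$n2 * p2^(p$n2 - 1) *
          (p$kappa2 * m2 - p$mu2 * p2) / d2^2,
      p$gamma2 * (p$gamma2 * m2 - p$lambda2 * Hm) -
        p$lambda2 * p$n1 * p$theta1^p$n1 * p1^(p$n1 - 1) *
          (p$kappa1 * m1 - p$mu1 * p1) / d1^2,
      -p$mu1 * (p$kappa1 * m1 - p$mu1 * p1) -
        p$kappa1 * (p$gamma1 * m1 - p$lambda1 * Hp),
      -p$mu2 * (p$kappa2 * m2 - p$mu2 * p2) -
        p$kappa2 * (p$gamma2 * m2 - p$lambda2 * Hm))
  }
  sys <- two_gene_system()
  set.seed(7)
  for (k in 1:10) {
    y <- stats::runif(4, 0.05, 2)
    expect_equal(sys$g(y), g_closed(y), tolerance = 1e-13)
  }
})

test_that("the generic N-gene builder reproduces the two-gene model", {
  p <- two_gene_params()
  spec <- list(
    N = 2,
    R = function(pp) c(p$lambda1 * hill("activation", pp[2], p$theta2, p$n2),
                       p$lambda2 * hill("inhibition", pp[1], p$theta1, p$n1)),
    dRdp = function(pp) {
      d1 <- p$theta1^p$n1 + pp[1]^p$n1
      d2 <- p$theta2^p$n2 + pp[2]^p$n2
      matrix(c(0, p$lambda1 * p$n2 * p$theta2^p$n2 * pp[2]^(p$n2 - 1) / d2^2,
               -p$lambda2 * p$n1 * p$theta1^p$n1 * pp[1]^(p$n1 - 1) / d1^2, 0),
             2, 2, byrow = TRUE)
    },
    kappa = 1, gamma = 1, mu = 1)
  gen <- n_gene_system(spec)
  ref <- two_gene_system()
  expect_identical(gen$dim, 4L)
  set.seed(11)
  for (k in 1:20) {
    y <- stats::runif(4, 0.05, 2)
    expect_lt(max(abs(gen$f(y) - ref$f(y))), 1e-14)
    expect_lt(max(abs(gen$jac(y) - ref$jac(y))), 1e-13)
  }
})

test_that("a one-gene constant-regulation system has the linear steady state", {
  r <- 0.8
  spec <- list(N = 1, R = function(p) r,
               dRdp = function(p) matrix(0, 1, 1),
               kappa = 1, gamma = 1, mu = 1)
  sys <- n_gene_system(spec)
  expect_identical(sys$dim, 2L)
  ss <- find_steady_state(sys, c(0.3, 0.3))
  expect_equal(unname(ss$y_star), c(r, r), tolerance = 1e-12)
})

test_that("the model registry resolves names and applies overrides", {
  sys <- get_model("two_gene", list(lambda1 = 1.3))
  expect_equal(sys$params$lambda1, 1.3)
  expect_identical(get_model("per")$dim, 5L)
  expect_error(get_model("nope"), "unknown model")
})
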