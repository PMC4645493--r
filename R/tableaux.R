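# Stage structure and frequency-dependent update weights.
#
# The four-stage explicit TDRK scheme advances
#   Y_i     = y_n + c_i h f(y_n) + h^2 sum_j a_ij g(Y_j)
#   y_{n+1} = eta(nu) y_n + h beta(nu) f(y_n) + h^2 sum_i b_i(nu) g(Y_i)
# with nu = omega * h.  The stage matrix A and abscissae c are fixed; only
# the update weights eta, beta, b_i depend on the fitting frequency.  At
# nu = 0 the weights reduce to the constant-coefficient prototype TDRK4s6.

# exact rational entries of the stage structure: c(num, den)
.TABLEAU_C <- list(c(0, 1), c(1, 4), c(2, 3), c(1, 1))
.TABLEAU_A <- list(
  list(),
  list(c(1, 32)),
  list(c(-2, 81), c(20, 81)),
  list(c(5, 4), c(-6, 5), c(9, 20))
)
.TABLEAU_B <- list(c(3, 40), c(64, 225), c(27, 200), c(1, 180))

#' The prototype (limit) TDRK4s6 tableau
#'
#' Returns the fixed stage structure shared by all methods in the family:
#' abscissae `c = (0, 1/4, 2/3, 1)`, the strictly lower-triangular stage
#' matrix `A`, and the limit update weights
#' `b = (3/40, 64/225, 27/200, 1/180)` with `eta = beta = 1`.  At
#' construction the simplifying assumption `A e = c^2 / 2` and the leading
#' quadrature conditions on `b` are re-verified in exact rational
#' arithmetic, so a corrupted entry stops the package immediately.
#'
#' @return An object of class `tdrk_tableau` with fields `s`, `c`, `A`,
#'   `b_limit`, `eta_limit`, `beta_limit` (doubles) and the exact rational
#'   forms `c_exact`, `A_exact`, `b_exact` (`c(num, den)` pairs).
#' @examples
#' tab <- limit_tableau()
#' tab$c                          # 0 1/4 2/3 1
#' rowSums(tab$A) - tab$c^2 / 2   # all zero
#' @export
limit_tableau <- function() {
  s <- 4L
  rr <- function(p) .rat(p[1], p[2])
  c_r <- lapply(.TABLEAU_C, rr)
  b_r <- lapply(.TABLEAU_B, rr)

  # row sums of A must equal c_i^2 / 2, checked exactly
  for (i in seq_len(s)) {
    acc <- .rat_zero()
    for (e in .TABLEAU_A[[i]]) acc <- .rat_add(acc, rr(e))
    target <- .rat_mul(.rat_mul(c_r[[i]], c_r[[i]]), .rat(1, 2))
    if (!.rat_eq(acc, target))
      stop(sprintf("tableau row %d violates A e = c^2/2", i))
  }
  # b . e = 1/2, b . c = 1/6, b . c^2 = 1/12 checked exactly
  dot_b <- function(w) {
    acc <- .rat_zero()
    for (i in seq_len(s)) acc <- .rat_add(acc, .rat_mul(b_r[[i]], w[[i]]))
    acc
  }
  one <- .rat(1)
  c2_r <- lapply(c_r, function(x) .rat_mul(x, x))
  checks <- list(
    list(rep(list(one), s), .rat(1, 2)),
    list(c_r, .rat(1, 6)),
    list(c2_r, .rat(1, 12))
  )
  for (ch in checks)
    if (!.rat_eq(dot_b(ch[[1]]), ch[[2]]))
      stop("tableau limit weights violate a quadrature condition")

  A <- matrix(0, s, s)
  for (i in seq_len(s))
    for (j in seq_along(.TABLEAU_A[[i]]))
      A[i, j] <- .TABLEAU_A[[i]][[j]][1] / .TABLEAU_A[[i]][[j]][2]

  structure(list(
    s = s,
    c = vapply(.TABLEAU_C, function(p) p[1] / p[2], numeric(1)),
    A = A,
    b_limit = vapply(.TABLEAU_B, function(p) p[1] / p[2], numeric(1)),
    eta_limit = 1,
    beta_limit = 1,
    c_exact = .TABLEAU_C,
    A_exact = .TABLEAU_A,
    b_exact = .TABLEAU_B
  ), class = "tdrk_tableau")
}

# ---------------------------------------------------------------------------
# Printed Taylor series of the update weights of the three fitted methods.
# Each coefficient is a list of (power, numerator, denominator) triples;
# denominators beyond double-integer range are decimal strings.  Only even
# powers occur.

.SERIES_TABLES <- list(
  a = list(
    eta = list(list(0, 1, 1),
               list(8, 23, 348364800),
               list(10, -2087, 222953472000)),
    beta = list(list(0, 1, 1),
                list(6, 1, 1209600),
                list(8, 1637, 20901888000),
                list(10, -3444061, 3973030871040000)),
    b1 = list(list(0, 3, 40),
              list(2, 1, 11200),
              list(4, -4601, 870912000),
              list(6, -36863647, 165542952960000),
              list(8, 248988432157, "86770994223513600000")),
    b2 = list(list(0, 64, 225),
              list(2, -1, 5250),
              list(4, 5407, 816480000),
              list(6, 52884329, 155196518400000),
              list(8, -391939117499, "81347807084544000000")),
    b3 = list(list(0, 27, 200),
              list(2, 9, 56000),
              list(4, 17, 17920000),
              list(6, -9073027, 91968307200000),
              list(8, 35868256579, "16068702633984000000")),
    b4 = list(list(0, 1, 180),
              list(2, -1, 16800),
              list(4, -427, 186624000),
              list(6, -4822283, 248314429440000),
              list(8, -36912938527, "130156491335270400000"))
  ),
  b = list(
    eta = list(list(0, 1, 1),
               list(8, 299, 136080000),
               list(10, -16561, 108864000000)),
    beta = list(list(0, 1, 1),
                list(6, 1, 189000),
                list(8, 12749, 8164800000),
                list(10, 9829099, 277136640000000)),
    b1 = list(list(0, 3, 40),
              list(2, 1, 4000),
              list(4, -159449, 5443200000),
              list(6, -328547263, 117573120000000),
              list(8, -168770118283, "3386105856000000000")),
    b2 = list(list(0, 64, 225),
              list(2, -1, 1875),
              list(4, 155713, 5103000000),
              list(6, 398361581, 110224800000000),
              list(8, 1477535874781, "34919216640000000000")),
    b3 = list(list(0, 27, 200),
              list(2, 9, 20000),
              list(4, 2153, 112000000),
              list(6, 16429997, 65318400000000),
              list(8, 374690334049, "6897623040000000000")),
    b4 = list(list(0, 1, 180),
              list(2, -1, 6000),
              list(4, -166921, 8164800000),
              list(6, -188918627, 176359680000000),
              list(8, -2614342153777, "55870746624000000000"))
  ),
  c = list(
    eta = list(list(0, 1, 1),
               list(8, 23, 1360800),
               list(10, -2087, 217728000)),
    beta = list(list(0, 1, 1),
                list(6, 1, 18900),
                list(8, 1637, 81648000),
                list(10, -3444061, 3879912960000)),
    b1 = list(list(0, 3, 40),
              list(2, 1, 2800),
              list(4, -4601, 54432000),
              list(6, -36863647, 2586608640000),
              list(8, 248988432157, "338949196185600000")),
    b2 = list(list(0, 64, 225),
              list(2, -2, 2625),
              list(4, 5407, 51030000),
              list(6, 52884329, 2424945600000),
              list(8, -391939117499, "317764871424000000")),
    b3 = list(list(0, 27, 200),
              list(2, 9, 14000),
              list(4, 17, 1120000),
              list(6, -9073027, 1437004800000),
              list(8, 35868256579, "62768369664000000")),
    b4 = list(list(0, 1, 180),
              list(2, -1, 4200),
              list(4, -427, 11664000),
              list(6, -4822283, 3879912960000),
              list(8, -36912938527, "508423794278400000"))
  )
)

.series_from_table <- function(entries) {
  order <- max(vapply(entries, function(e) e[[1]], numeric(1)))
  num <- as.list(rep(0, order + 1))
  den <- as.list(rep(1, order + 1))
  for (e in entries) {
    num[[e[[1]] + 1L]] <- e[[2]]
    den[[e[[1]] + 1L]] <- e[[3]]
  }
  power_series(num, den, order = order)
}

#' Truncated Taylor series of one method's update weights
#'
#' Returns the power series in `nu` of `eta`, `beta` and the four update
#' weights `b_i` for one of the fitted methods, with exact rational
#' coefficients and the truncation order of each series as tabulated
#' (`nu^10` for `eta`/`beta`, `nu^8` for the `b_i`).  The constant terms
#' are the prototype weights; only even powers occur, so every weight is
#' an even function of `nu`.
#'
#' @param method_id `"a"`, `"b"` or `"c"`, selecting EFTDRK4s6a/b/c.
#' @return An object of class `coefficient_series`: a list with
#'   `method_id`, `eta`, `beta` (each a [power_series]) and `b`, a list
#'   of four [power_series].
#' @examples
#' cs <- coefficient_series("a")
#' ps_coef_is(cs$b[[1]], 2, 1, 11200)  # TRUE
#' @export
coefficient_series <- function(method_id = c("a", "b", "c")) {
  method_id <- match.arg(method_id)
  tabs <- .SERIES_TABLES[[method_id]]
  structure(list(
    method_id = method_id,
    eta = .series_from_table(tabs$eta),
    beta = .series_from_table(tabs$beta),
    b = lapply(paste0("b", 1:4), function(k) .series_from_table(tabs[[k]]))
  ), class = "coefficient_series")
}

.new_fitted_weights <- function(nu, eta, beta, b, method_id, source) {
  structure(list(nu = nu, eta = eta, beta = beta, b = b,
                 method_id = method_id, source = source),
            class = "fitted_weights")
}

#' @export
print.fitted_weights <- function(x, ...) {
  cat(sprintf("fitted weights, method %s at nu = %g (%s)\n",
              x$method_id, x$nu, x$source))
  cat(sprintf("  eta = %.15g, beta = %.15g\n", x$eta, x$beta))
  cat(sprintf("  b   = %.15g %.15g %.15g %.15g\n",
              x$b[1], x$b[2], x$b[3], x$b[4]))
  invisible(x)
}

# The tabulated series truncate at nu^8/nu^10 with rapidly decaying
# coefficients; for |nu| <= 1.5 the dropped tail is below ~1e-12 in every
# coefficient, which is the documented validity radius.
.SERIES_RADIUS <- 1.5

# switch point below which the trigonometric solve for method a is replaced
# by the series: right-hand sides like (eta - cos nu)/nu^2 cancel
# catastrophically as nu -> 0
.SERIES_SWITCH_A <- 0.05

#' Evaluate the printed weight series of one fitted method
#'
#' @param method_id `"a"`, `"b"` or `"c"`.
#' @param nu scaled frequency `omega * h` (dimensionless).  Beyond the
#'   documented validity radius `|nu| <= 1.5` a warning is recorded but
#'   the value is still returned.
#' @return A `fitted_weights` object with `source = "series"`.  At
#'   `nu = 0` the prototype weights are returned exactly.
#' @examples
#' weights_series("b", 0)$b[2]  # 64/225
#' @export
weights_series <- function(method_id = c("a", "b", "c"), nu) {
  method_id <- match.arg(method_id)
  stopifnot(is.numeric(nu), length(nu) == 1L, is.finite(nu))
  if (abs(nu) > .SERIES_RADIUS)
    warning(sprintf(
      "|nu| = %.3g exceeds the series validity radius %.2g; truncation error may be significant",
      abs(nu), .SERIES_RADIUS))
  cs <- coefficient_series(method_id)
  .new_fitted_weights(
    nu = nu,
    eta = ps_eval(cs$eta, nu),
    beta = ps_eval(cs$beta, nu),
    b = vapply(cs$b, ps_eval, numeric(1), nu = nu),
    method_id = method_id,
    source = "series")
}

# the 6x6 linear fitting system for method a at one nu:
# rows = defect on exp(i w t) (real, imag), defect on t exp(i w t)
# (real, imag), plus the quadrature conditions b.e = 1/2, b.c = 1/6;
# unknowns x = (eta, beta, b1, b2, b3, b4)
.weights_a_system <- function(nu) {
  cc <- c(0, 1 / 4, 2 / 3, 1)
  s <- sin(cc * nu); co <- cos(cc * nu)
  M <- rbind(
    c(0, -nu, 0, nu^2 * s[2], nu^2 * s[3], nu^2 * s[4]),
    c(-1, 0, nu^2, nu^2 * co[2], nu^2 * co[3], nu^2 * co[4]),
    c(0, -1, 0,
      nu^2 * cc[2] * co[2] + 2 * nu * s[2],
      nu^2 * cc[3] * co[3] + 2 * nu * s[3],
      nu^2 * cc[4] * co[4] + 2 * nu * s[4]),
    c(0, 0, 2 * nu,
      2 * nu * co[2] - nu^2 * cc[2] * s[2],
      2 * nu * co[3] - nu^2 * cc[3] * s[3],
      2 * nu * co[4] - nu^2 * cc[4] * s[4]),
    c(0, 0, 1, 1, 1, 1),
    c(0, 0, 0, cc[2], cc[3], cc[4])
  )
  rhs <- c(-sin(nu), -cos(nu), -cos(nu), sin(nu), 1 / 2, 1 / 6)
  list(M = M, rhs = rhs)
}

#' Update weights of EFTDRK4s6a at one scaled frequency
#'
#' For `|nu|` at or above the switch threshold 0.05 the six exponential
#' fitting equations -- vanishing of the one-step defect on
#' `exp(+-i omega t)` and `t exp(+-i omega t)`, plus the quadrature
#' conditions `b.e = 1/2` and `b.c = 1/6` -- are solved as a 6x6 linear
#' system in `(eta, beta, b1..b4)` and the residual of all six equations
#' is verified to be below 1e-12.  The system's condition number grows
#' like `nu^-3`, so the solve runs in extended precision with iterative
#' refinement.  Below the threshold the right-hand sides cancel
#' catastrophically and the printed Taylor series is evaluated instead
#' (`source = "series"`).
#'
#' @param nu scaled frequency `omega * h` (dimensionless, may be 0).
#' @return A `fitted_weights` object; `source` records which branch
#'   produced the values.
#' @examples
#' weights_a(0)$b          # prototype weights
#' weights_a(1.0)$source   # "exact_solve"
#' @export
weights_a <- function(nu) {
  stopifnot(is.numeric(nu), length(nu) == 1L, is.finite(nu))
  if (abs(nu) < .SERIES_SWITCH_A)
    return(weights_series("a", nu))
  x <- .solve_weights_a_cpp(nu)
  sys <- .weights_a_system(nu)
  if (anyNA(x)) {
    warning(sprintf(
      "fitting system singular at nu = %g; falling back to series", nu))
    return(weights_series("a", nu))
  }
  resid <- max(abs(sys$M %*% x - sys$rhs))
  if (resid > 1e-12) {
    warning(sprintf(
      "fitting residual %.2g at nu = %g exceeds 1e-12; falling back to series",
      resid, nu))
    return(weights_series("a", nu))
  }
  .new_fitted_weights(nu = nu, eta = x[1], beta = x[2], b = x[3:6],
                      method_id = "a", source = "exact_solve")
}

#' Update weights for any method of the family
#'
#' Dispatch helper used by the integrators: the prototype returns the
#' limit weights for every `nu`; method `"a"` uses [weights_a()] (exact
#' trigonometric solve away from 0); methods `"b"` and `"c"` are defined
#' by their printed truncated series.
#'
#' @param method one of `"prototype"`, `"a"`, `"b"`, `"c"` (the aliases
#'   `"efa"`, `"efb"`, `"efc"` are accepted).
#' @param nu scaled frequency `omega * h`.
#' @return A `fitted_weights` object.
#' @export
fitted_weights <- function(method, nu = 0) {
  method <- sub("^ef", "", method)
  if (method == "prototype" || nu == 0) {
    tab <- limit_tableau()
    id <- if (method %in% c("a", "b", "c")) method else "prototype"
    if (!method %in% c("prototype", "a", "b", "c"))
      stop(sprintf("unknown method '%s'", method))
    return(.new_fitted_weights(nu = nu, eta = 1, beta = 1, b = tab$b_limit,
                               method_id = id, source = "exact_solve"))
  }
  switch(method,
    a = weights_a(nu),
    b = weights_series("b", nu),
    c = weights_series("c", nu),
    stop(sprintf("unknown method '%s'", method)))
}
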