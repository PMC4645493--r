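# Verification of the sixth-order conditions and of the exponential
# fitting property.
#
# The order conditions couple the nu-dependent weight series b(nu) with
# rational tableau quantities (c, powers of c, A c, ...).  Everything is
# checked coefficientwise in exact rational arithmetic -- no
# floating-point sampling -- so a single wrong digit in a transcribed
# series coefficient is caught exactly.

# rational 4-vectors derived from the tableau
.tableau_vectors <- function(tableau) {
  s <- tableau$s
  rr <- function(p) .rat(p[1], p[2])
  cv <- lapply(tableau$c_exact, rr)
  Ar <- lapply(tableau$A_exact, function(row) lapply(row, rr))
  vmul <- function(x, y) mapply(.rat_mul, x, y, SIMPLIFY = FALSE)
  Avec <- function(v) lapply(seq_len(s), function(i) {
    acc <- .rat_zero()
    row <- Ar[[i]]
    for (j in seq_along(row)) acc <- .rat_add(acc, .rat_mul(row[[j]], v[[j]]))
    acc
  })
  e <- rep(list(.rat(1)), s)
  c2 <- vmul(cv, cv)
  c3 <- vmul(c2, cv)
  c4 <- vmul(c3, cv)
  Ac <- Avec(cv)
  Ae <- Avec(e)
  list(e = e, c = cv, c2 = c2, c3 = c3, c4 = c4,
       Ac = Ac, cAc = vmul(cv, Ac), Ac2 = Avec(c2),
       Ae = Ae, cAe = vmul(cv, Ae), c2Ae = vmul(c2, Ae),
       AeAe = vmul(Ae, Ae), A2e = Avec(Ae))
}

# one condition: series == target + O(nu^req), i.e. constant term equals
# target and coefficients 1 .. req-1 vanish
.check_condition <- function(series, target, req) {
  checkable_to <- min(series$order, req - 1L)
  first_bad <- NA_integer_
  if (!.rat_eq(series$coef[[1]], target)) first_bad <- 0L
  if (is.na(first_bad) && checkable_to >= 1L) {
    for (k in seq_len(checkable_to)) {
      if (series$coef[[k + 1L]]$s != 0) { first_bad <- k; break }
    }
  }
  list(passed = is.na(first_bad),
       checkable = series$order >= req - 1L,
       first_offending_power = first_bad)
}

#' Check the ten sixth-order conditions for a coefficient series
#'
#' For each condition -- `b.e = 1/2 + O(nu^5)`, `b.c = 1/6 + O(nu^4)`,
#' `b.c^2 = 1/12 + O(nu^3)`, `b.c^3 = 1/20 + O(nu^2)`,
#' `b.Ac = 1/120 + O(nu^2)`, `b.c^4 = 1/30 + O(nu)`,
#' `b.(c*Ac) = 1/180 + O(nu)`, `b.Ac^2 = 1/360 + O(nu)`, plus
#' `eta = 1 + O(nu^7)` and `beta = 1 + O(nu^6)` -- the left-hand side is
#' formed as a [power_series] from the tableau's exact rationals and the
#' required leading coefficients are asserted exactly.  A condition whose
#' required order exceeds the series truncation is reported as not fully
#' checkable, never silently passed.
#'
#' With `full = TRUE` the five additional conditions of the
#' pre-simplification list (those that the row-sum assumption
#' `A e = c^2/2` makes redundant: `b.Ae = 1/24 + O(nu^3)`,
#' `b.(c*Ae) = 1/40 + O(nu^2)`, `b.(c^2*Ae) = 1/60 + O(nu)`,
#' `b.(Ae*Ae) = 1/120 + O(nu)`, `b.A^2e = 1/720 + O(nu)`) are checked as
#' well, with `A e` computed from the stage matrix rather than
#' substituted.
#'
#' @param cs a `coefficient_series` from [coefficient_series()].
#' @param tableau a `tdrk_tableau`.
#' @param full also check the pre-simplification conditions.
#' @return A data frame with one row per condition: `condition`,
#'   `required_order` (the power in the O() term), `checkable`,
#'   `passed`, `first_offending_power`.  Attribute `all_pass` is `TRUE`
#'   when every checkable condition passed.
#' @examples
#' rep <- check_order_conditions(coefficient_series("a"))
#' attr(rep, "all_pass")  # TRUE
#' @export
check_order_conditions <- function(cs, tableau = limit_tableau(),
                                   full = FALSE) {
  stopifnot(inherits(cs, "coefficient_series"),
            inherits(tableau, "tdrk_tableau"))
  v <- .tableau_vectors(tableau)
  conds <- list(
    list("eta = 1 + O(nu^7)",        cs$eta,  .rat(1),      7L),
    list("beta = 1 + O(nu^6)",       cs$beta, .rat(1),      6L),
    list("b.e = 1/2 + O(nu^5)",      .ps_weighted_sum(cs$b, v$e),   .rat(1, 2),   5L),
    list("b.c = 1/6 + O(nu^4)",      .ps_weighted_sum(cs$b, v$c),   .rat(1, 6),   4L),
    list("b.c^2 = 1/12 + O(nu^3)",   .ps_weighted_sum(cs$b, v$c2),  .rat(1, 12),  3L),
    list("b.c^3 = 1/20 + O(nu^2)",   .ps_weighted_sum(cs$b, v$c3),  .rat(1, 20),  2L),
    list("b.Ac = 1/120 + O(nu^2)",   .ps_weighted_sum(cs$b, v$Ac),  .rat(1, 120), 2L),
    list("b.c^4 = 1/30 + O(nu)",     .ps_weighted_sum(cs$b, v$c4),  .rat(1, 30),  1L),
    list("b.(c*Ac) = 1/180 + O(nu)", .ps_weighted_sum(cs$b, v$cAc), .rat(1, 180), 1L),
    list("b.Ac^2 = 1/360 + O(nu)",   .ps_weighted_sum(cs$b, v$Ac2), .rat(1, 360), 1L)
  )
  if (full) {
    conds <- c(conds, list(
      list("b.Ae = 1/24 + O(nu^3)",       .ps_weighted_sum(cs$b, v$Ae),   .rat(1, 24),  3L),
      list("b.(c*Ae) = 1/40 + O(nu^2)",   .ps_weighted_sum(cs$b, v$cAe),  .rat(1, 40),  2L),
      list("b.(c^2*Ae) = 1/60 + O(nu)",   .ps_weighted_sum(cs$b, v$c2Ae), .rat(1, 60),  1L),
      list("b.(Ae*Ae) = 1/120 + O(nu)",   .ps_weighted_sum(cs$b, v$AeAe), .rat(1, 120), 1L),
      list("b.A^2e = 1/720 + O(nu)",      .ps_weighted_sum(cs$b, v$A2e),  .rat(1, 720), 1L)
    ))
  }
  rows <- lapply(conds, function(cd) {
    r <- .check_condition(cd[[2]], cd[[3]], cd[[4]])
    data.frame(condition = cd[[1]], required_order = cd[[4]],
               checkable = r$checkable, passed = r$passed,
               first_offending_power = r$first_offending_power)
  })
  out <- do.call(rbind, rows)
  attr(out, "all_pass") <- all(out$passed)
  out
}

# reference functions for the one-step defect, with exact first and
# second derivatives; w is the fitting frequency omega
.ref_functions <- list(
  one = function(t, w) list(y = 1 + 0i, d1 = 0i, d2 = 0i),
  t = function(t, w) list(y = t + 0i, d1 = 1 + 0i, d2 = 0i),
  t_sq = function(t, w) list(y = t^2 + 0i, d1 = 2 * t + 0i, d2 = 2 + 0i),
  t_cubed = function(t, w) list(y = t^3 + 0i, d1 = 3 * t^2 + 0i,
                                d2 = 6 * t + 0i),
  exp_iwt = function(t, w) {
    e <- exp(1i * w * t)
    list(y = e, d1 = 1i * w * e, d2 = -w^2 * e)
  },
  t_exp_iwt = function(t, w) {
    e <- exp(1i * w * t)
    list(y = t * e, d1 = (1 + 1i * w * t) * e,
         d2 = (2i * w - w^2 * t) * e)
  },
  exp_2iwt = function(t, w) {
    e <- exp(2i * w * t)
    list(y = e, d1 = 2i * w * e, d2 = -4 * w^2 * e)
  },
  t_exp_2iwt = function(t, w) {
    e <- exp(2i * w * t)
    list(y = t * e, d1 = (1 + 2i * w * t) * e,
         d2 = (4i * w - 4 * w^2 * t) * e)
  },
  t_sq_exp_2iwt = function(t, w) {
    e <- exp(2i * w * t)
    list(y = t^2 * e, d1 = (2 * t + 2i * w * t^2) * e,
         d2 = (2 + 8i * w * t - 4 * w^2 * t^2) * e)
  }
)

#' One-step defect of a fitted method on a reference function
#'
#' Evaluates the linear defect operator
#' `L[y](t) = y(t+h) - eta(nu) y(t) - h beta(nu) y'(t)
#'            - h^2 sum_i b_i(nu) y''(t + c_i h)`
#' using exact analytic derivatives of the chosen reference function,
#' with the method's weights at `nu`.  For functions in a method's
#' reference set the residual vanishes to within the accuracy of the
#' weight source (machine level for the exact solve of method a; the
#' series truncation bound for methods b and c).  For functions outside
#' the set the residual is decisively nonzero, so the check
#' discriminates.
#'
#' @param method_id `"a"`, `"b"`, `"c"` or `"prototype"`.
#' @param nu scaled frequency `omega * h`, with `omega = nu / h`.
#' @param ref_function one of `"one"`, `"t"`, `"t_sq"`, `"t_cubed"`,
#'   `"exp_iwt"`, `"t_exp_iwt"`, `"exp_2iwt"`, `"t_exp_2iwt"`,
#'   `"t_sq_exp_2iwt"`.
#' @param t evaluation time.
#' @param h step size (> 0).
#' @return The complex residual `L[y](t)`.
#' @examples
#' abs(fitting_residual("a", 0.5, "exp_iwt", t = 1.3, h = 0.5))  # ~1e-16
#' @export
fitting_residual <- function(method_id, nu, ref_function, t, h) {
  stopifnot(is.numeric(nu), length(nu) == 1L, h > 0)
  fn <- .ref_functions[[ref_function]]
  if (is.null(fn))
    stop(sprintf("unknown reference function '%s'", ref_function))
  w <- fitted_weights(method_id, nu)
  omega <- nu / h
  tab <- limit_tableau()
  at_t <- fn(t, omega)
  y_next <- fn(t + h, omega)$y
  acc <- 0i
  for (i in 1:4) acc <- acc + w$b[i] * fn(t + tab$c[i] * h, omega)$d2
  y_next - w$eta * at_t$y - h * w$beta * at_t$d1 - h^2 * acc
}
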