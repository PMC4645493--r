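# Truncated power series in nu with exact rational coefficients.
#
# Several printed weight-series denominators exceed 2^53, so coefficients
# cannot live in doubles.  A minimal non-negative big integer (numeric
# limbs, base 2^24) backs an unreduced exact rational type: equality is
# decided by cross-multiplication, so no gcd is ever needed.  All
# order-condition checks run on these exact rationals; doubles appear
# only when a series is *evaluated*.

.BIGBASE <- 2^24

# carry-propagate and strip high zero limbs
.big_norm <- function(v) {
  i <- 1L
  while (i <= length(v)) {
    if (v[i] >= .BIGBASE) {
      q <- floor(v[i] / .BIGBASE)
      v[i] <- v[i] - q * .BIGBASE
      if (i == length(v)) v <- c(v, 0)
      v[i + 1L] <- v[i + 1L] + q
    }
    i <- i + 1L
  }
  n <- length(v)
  while (n > 1L && v[n] == 0) n <- n - 1L
  v[seq_len(n)]
}

.big_from_num <- function(x) {
  stopifnot(is.finite(x), x >= 0, x == round(x), x < 2^53)
  if (x == 0) return(0)
  v <- numeric(0)
  while (x > 0) {
    r <- x %% .BIGBASE
    v <- c(v, r)
    x <- (x - r) / .BIGBASE
  }
  v
}

.big_smul <- function(v, k) .big_norm(v * k)  # k small non-negative integer

.big_from_dec <- function(s) {
  digits <- as.integer(strsplit(s, "")[[1]])
  if (any(is.na(digits))) stop("invalid decimal integer string: ", s)
  v <- 0
  for (d in digits) {
    v <- .big_smul(v, 10)
    v[1] <- v[1] + d
    v <- .big_norm(v)
  }
  v
}

.big_is_zero <- function(v) length(v) == 1L && v[1] == 0

.big_cmp <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  for (i in rev(seq_len(n))) {
    if (a[i] > b[i]) return(1L)
    if (a[i] < b[i]) return(-1L)
  }
  0L
}

.big_add <- function(a, b) {
  n <- max(length(a), length(b))
  .big_norm(c(a, rep(0, n - length(a))) + c(b, rep(0, n - length(b))))
}

.big_sub <- function(a, b) { # requires a >= b
  n <- length(a)
  v <- a - c(b, rep(0, n - length(b)))
  for (i in seq_len(n)) {
    if (v[i] < 0) {
      v[i] <- v[i] + .BIGBASE
      v[i + 1L] <- v[i + 1L] - 1
    }
  }
  while (n > 1L && v[n] == 0) n <- n - 1L
  v[seq_len(n)]
}

.big_mul <- function(a, b) {
  if (.big_is_zero(a) || .big_is_zero(b)) return(0)
  if (min(length(a), length(b)) > 32L)
    stop("big integer multiplication operand too long for exact limb arithmetic")
  n <- length(a) + length(b)
  out <- numeric(n)
  carry <- 0
  for (k in seq_len(n)) {
    s <- carry
    jlo <- max(1L, k - length(b) + 1L)
    jhi <- min(length(a), k)
    if (jlo <= jhi)
      for (j in jlo:jhi) s <- s + a[j] * b[k - j + 1L]
    carry <- floor(s / .BIGBASE)
    out[k] <- s - carry * .BIGBASE
  }
  stopifnot(carry == 0)
  m <- n
  while (m > 1L && out[m] == 0) m <- m - 1L
  out[seq_len(m)]
}

.big_to_num <- function(v, drop = 0L) {
  if (drop > 0L) v <- v[-seq_len(min(drop, length(v) - 1L))]
  x <- 0
  for (i in rev(seq_along(v))) x <- x * .BIGBASE + v[i]
  x
}

# ---- signed exact rationals (unreduced) -----------------------------------

# build from integer-valued double or decimal string (possibly signed)
.rat <- function(num, den = 1) {
  parse_part <- function(x) {
    if (is.character(x)) {
      s <- 1
      if (startsWith(x, "-")) { s <- -1; x <- substring(x, 2) }
      list(s = s, v = .big_from_dec(x))
    } else {
      list(s = if (x < 0) -1 else 1, v = .big_from_num(abs(x)))
    }
  }
  n <- parse_part(num)
  d <- parse_part(den)
  if (.big_is_zero(d$v)) stop("zero denominator")
  s <- n$s * d$s
  if (.big_is_zero(n$v)) s <- 0
  structure(list(s = s, n = n$v, d = d$v), class = "eftdrk_rational")
}

.rat_is_rat <- function(x) inherits(x, "eftdrk_rational")

# signed magnitude addition: (s1, v1) + (s2, v2)
.signed_add <- function(s1, v1, s2, v2) {
  if (s1 == 0) return(list(s = s2, v = v2))
  if (s2 == 0) return(list(s = s1, v = v1))
  if (s1 == s2) return(list(s = s1, v = .big_add(v1, v2)))
  cmp <- .big_cmp(v1, v2)
  if (cmp == 0) return(list(s = 0, v = 0))
  if (cmp > 0) list(s = s1, v = .big_sub(v1, v2))
  else list(s = s2, v = .big_sub(v2, v1))
}

.rat_add <- function(x, y) {
  a <- .big_mul(x$n, y$d)
  b <- .big_mul(y$n, x$d)
  r <- .signed_add(x$s, a, y$s, b)
  structure(list(s = r$s, n = r$v, d = .big_mul(x$d, y$d)),
            class = "eftdrk_rational")
}

.rat_mul <- function(x, y) {
  s <- x$s * y$s
  n <- .big_mul(x$n, y$n)
  if (.big_is_zero(n)) s <- 0
  structure(list(s = s, n = n, d = .big_mul(x$d, y$d)),
            class = "eftdrk_rational")
}

.rat_neg <- function(x) { x$s <- -x$s; x }

.rat_eq <- function(x, y) {
  r <- .signed_add(x$s, .big_mul(x$n, y$d), -y$s, .big_mul(y$n, x$d))
  r$s == 0
}

.rat_to_num <- function(x) {
  drop <- max(0L, min(length(x$n), length(x$d)) - 20L)
  x$s * .big_to_num(x$n, drop) / .big_to_num(x$d, drop)
}

.rat_zero <- function() .rat(0)

# ---- truncated power series -----------------------------------------------

#' Truncated power series with exact rational coefficients
#'
#' Constructs a power series in the scaled frequency `nu`, truncated at
#' `order`: coefficients of powers above `order` are *unknown*, not zero.
#' Coefficients are exact rationals; numerators and denominators may be
#' given as integer-valued numbers or, for values beyond double-integer
#' range, as decimal strings.
#'
#' @param num vector (numeric or character) of numerators, power 0 first.
#' @param den vector of denominators, recycled to the length of `num`.
#' @param order truncation order `K`; defaults to `length(num) - 1`.  If
#'   larger, the series is padded with exact zeros up to power `K`.
#' @return An object of class `power_series` with a list of exact
#'   rational coefficients and the truncation order.
#' @examples
#' p <- series_arith("mul", power_series(c(1, 1)), power_series(c(1, -1)))
#' ps_coef(p, 2)  # -1: (1 + nu)(1 - nu) = 1 - nu^2
#' @export
power_series <- function(num, den = 1, order = length(num) - 1L) {
  if (length(den) == 1L) den <- rep(den, length(num))
  stopifnot(length(num) == length(den))
  coef <- lapply(seq_along(num), function(i) .rat(num[[i]], den[[i]]))
  if (length(coef) > order + 1L)
    stop("more coefficients than the truncation order allows")
  while (length(coef) < order + 1L) coef[[length(coef) + 1L]] <- .rat_zero()
  structure(list(coef = coef, order = as.integer(order)),
            class = "power_series")
}

#' @export
print.power_series <- function(x, ...) {
  terms <- character(0)
  for (k in seq_along(x$coef)) {
    r <- x$coef[[k]]
    if (r$s == 0) next
    val <- .rat_to_num(r)
    terms <- c(terms,
               if (k == 1) sprintf("%.6g", val)
               else sprintf("(%.6g) nu^%d", val, k - 1L))
  }
  if (!length(terms)) terms <- "0"
  cat(paste(terms, collapse = " + "), sprintf("+ O(nu^%d)\n", x$order + 1L))
  invisible(x)
}

#' Extract one coefficient of a power series as a double
#'
#' @param x a `power_series`.
#' @param power the power of `nu`; must not exceed the truncation order.
#' @return The coefficient converted to double.
#' @export
ps_coef <- function(x, power) {
  stopifnot(inherits(x, "power_series"))
  if (power > x$order)
    stop(sprintf("coefficient of nu^%d is beyond the truncation order %d",
                 power, x$order))
  .rat_to_num(x$coef[[power + 1L]])
}

#' Exact rational test of one coefficient of a power series
#'
#' Decides `coef(nu^power) == num/den` in exact arithmetic
#' (cross-multiplication of unreduced big-integer rationals), so it
#' cannot be fooled by floating-point rounding.
#'
#' @param x a `power_series`.
#' @param power the power of `nu` to inspect.
#' @param num,den the expected rational value (numeric or decimal string).
#' @return `TRUE` or `FALSE`.
#' @export
ps_coef_is <- function(x, power, num, den = 1) {
  stopifnot(inherits(x, "power_series"))
  if (power > x$order)
    stop(sprintf("coefficient of nu^%d is beyond the truncation order %d",
                 power, x$order))
  .rat_eq(x$coef[[power + 1L]], .rat(num, den))
}

#' Evaluate a truncated power series at a numeric point
#'
#' Horner evaluation in double precision; the truncation tail is dropped.
#'
#' @param x a `power_series`.
#' @param nu numeric point(s).
#' @return Numeric vector of the same length as `nu`.
#' @export
ps_eval <- function(x, nu) {
  stopifnot(inherits(x, "power_series"))
  coefs <- vapply(x$coef, .rat_to_num, numeric(1))
  out <- rep(coefs[length(coefs)], length(nu))
  for (k in rev(seq_len(length(coefs) - 1L)))
    out <- out * nu + coefs[k]
  out
}

#' Arithmetic on truncated power series
#'
#' Exact rational arithmetic that tracks truncation: the result of
#' combining series of truncation orders K and L is only valid to
#' `min(K, L)` and is truncated there.
#'
#' @param op one of `"add"`, `"sub"`, `"mul"` (both arguments series) or
#'   `"scale"` (`y` a rational scalar).
#' @param x a `power_series`.
#' @param y a `power_series`, or for `"scale"` a scalar given as a single
#'   integer, a `c(num, den)` pair, or decimal strings.
#' @return A `power_series`.
#' @export
series_arith <- function(op = c("add", "sub", "mul", "scale"), x, y) {
  op <- match.arg(op)
  stopifnot(inherits(x, "power_series"))
  if (op == "scale") {
    r <- if (.rat_is_rat(y)) y
         else if (length(y) == 2L) .rat(y[[1]], y[[2]])
         else .rat(y[[1]])
    coef <- lapply(x$coef, .rat_mul, y = r)
    return(structure(list(coef = coef, order = x$order),
                     class = "power_series"))
  }
  stopifnot(inherits(y, "power_series"))
  K <- min(x$order, y$order)
  coef <- vector("list", K + 1L)
  if (op %in% c("add", "sub")) {
    for (i in seq_len(K + 1L)) {
      yy <- if (op == "sub") .rat_neg(y$coef[[i]]) else y$coef[[i]]
      coef[[i]] <- .rat_add(x$coef[[i]], yy)
    }
  } else { # mul
    for (k in 0:K) {
      acc <- .rat_zero()
      for (j in 0:k)
        acc <- .rat_add(acc, .rat_mul(x$coef[[j + 1L]], y$coef[[k - j + 1L]]))
      coef[[k + 1L]] <- acc
    }
  }
  structure(list(coef = coef, order = K), class = "power_series")
}

# internal: sum_i w_i * b_i with rational weights w (list of rationals)
.ps_weighted_sum <- function(b_list, w) {
  acc <- NULL
  for (i in seq_along(b_list)) {
    term <- series_arith("scale", b_list[[i]], w[[i]])
    acc <- if (is.null(acc)) term else series_arith("add", acc, term)
  }
  acc
}
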