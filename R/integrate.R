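# Fixed-step time stepping.
#
# The TDRK stepper costs 1 f-evaluation and 4 g-evaluations per step; the
# classical RK6 baseline costs 7 f-evaluations.  For the two built-in
# models the step loop runs in compiled code; user-supplied systems take
# the equivalent R path.  The fitting frequency is fixed for a whole run:
# nu = omega * h is computed once and the weights solved once.

#' One step of the (modified) TDRK method
#'
#' Computes the four stages `Y_i = y + c_i h f(y) + h^2 sum_j a_ij g(Y_j)`
#' explicitly in order (`Y_1 = y` since `c_1 = 0`), then returns
#' `eta y + h beta f(y) + h^2 sum_i b_i g(Y_i)`.  Exactly one evaluation
#' of `f` and four of `g`.
#'
#' @param system an `ode_system`.
#' @param y current state.
#' @param h step size (> 0).
#' @param tableau a `tdrk_tableau` (defaults to [limit_tableau()]).
#' @param weights a `fitted_weights` object (defaults to the prototype
#'   weights, i.e. `nu = 0`).
#' @return The state after one step.
#' @examples
#' sys <- two_gene_system()
#' tdrk_step(sys, c(0.6, 0.8, 0.4, 0.6), 0.25)
#' @export
tdrk_step <- function(system, y, h, tableau = limit_tableau(),
                      weights = fitted_weights("prototype")) {
  stopifnot(inherits(system, "ode_system"), h > 0,
            length(y) == system$dim)
  fy <- system$f(y)
  h2 <- h * h
  cc <- tableau$c
  A <- tableau$A
  gY <- vector("list", 4L)
  for (i in 1:4) {
    Yi <- y + cc[i] * h * fy
    if (i > 1L)
      for (j in 1:(i - 1L))
        if (A[i, j] != 0) Yi <- Yi + h2 * A[i, j] * gY[[j]]
    gY[[i]] <- system$g(Yi)
    if (!all(is.finite(gY[[i]])))
      stop(sprintf("non-finite state at stage %d", i))
  }
  b <- weights$b
  out <- weights$eta * y + h * weights$beta * fy +
    h2 * (b[1] * gY[[1]] + b[2] * gY[[2]] + b[3] * gY[[3]] + b[4] * gY[[4]])
  if (!all(is.finite(out))) stop("non-finite state after update")
  out
}

#' Seven-stage classical Runge-Kutta tableau of order six
#'
#' Butcher's explicit 7-stage method of algebraic order six, used as the
#' single-derivative baseline.  Results obtained with it are labelled
#' `"rk6 (baseline)"`; its coefficients are a standard published choice
#' and may differ from other order-six tableaux in the literature.
#'
#' @return A list with fields `s = 7`, `c`, `A`, `b`.
#' @examples
#' sum(rk6_baseline_tableau()$b)  # 1
#' @export
rk6_baseline_tableau <- function() {
  A <- matrix(0, 7, 7)
  A[2, 1] <- 1 / 3
  A[3, 1:2] <- c(0, 2 / 3)
  A[4, 1:3] <- c(1 / 12, 1 / 3, -1 / 12)
  A[5, 1:4] <- c(-1 / 16, 9 / 8, -3 / 16, -3 / 8)
  A[6, 1:5] <- c(0, 9 / 8, -3 / 8, -3 / 4, 1 / 2)
  A[7, 1:6] <- c(9 / 44, -9 / 11, 63 / 44, 18 / 11, 0, -16 / 11)
  list(s = 7L,
       c = c(0, 1 / 3, 2 / 3, 1 / 3, 1 / 2, 1 / 2, 1),
       A = A,
       b = c(11 / 120, 0, 27 / 40, 27 / 40, -4 / 15, -4 / 15, 11 / 120))
}

.rk_step <- function(system, y, h, tab) {
  K <- vector("list", tab$s)
  for (i in seq_len(tab$s)) {
    Yi <- y
    if (i > 1L)
      for (j in 1:(i - 1L))
        if (tab$A[i, j] != 0) Yi <- Yi + h * tab$A[i, j] * K[[j]]
    K[[i]] <- system$f(Yi)
  }
  acc <- 0
  for (i in seq_len(tab$s)) acc <- acc + tab$b[i] * K[[i]]
  out <- y + h * acc
  if (!all(is.finite(out))) stop("non-finite state after update")
  out
}

.resolve_step_count <- function(t0, t_end, h) {
  span <- t_end - t0
  n <- round(span / h)
  if (abs(n * h - span) > 1e-9 * h)
    stop(sprintf("step size %g does not divide the interval [%g, %g]",
                 h, t0, t_end))
  as.integer(n)
}

.new_trajectory <- function(times, states, system, method, h, omega, nu,
                            n_f, n_g, source) {
  colnames(states) <- system$state_names
  structure(list(times = times, states = states, method = method,
                 model = system$name, h = h, omega = omega, nu = nu,
                 eval_counts = list(n_f = n_f, n_g = n_g),
                 weight_source = source),
            class = "eftdrk_trajectory")
}

#' @export
print.eftdrk_trajectory <- function(x, ...) {
  cat(sprintf(
    "trajectory: model %s, method %s, h = %g, omega = %g, %d states\n",
    x$model, x$method, x$h, x$omega, length(x$times)))
  cat(sprintf("  evaluations: n_f = %d, n_g = %d\n",
              x$eval_counts$n_f, x$eval_counts$n_g))
  invisible(x)
}

#' Fixed-step integration with a TDRK-family method or the RK6 baseline
#'
#' Integrates from `t0` to `t_end` in `n = (t_end - t0)/h` equal steps
#' (`h` must divide the interval to within `1e-9 h`).  For the fitted
#' methods the scaled frequency `nu = omega * h` is fixed for the whole
#' run and the update weights are computed once.  The two built-in models
#' run in compiled code; any other `ode_system` takes the equivalent R
#' stepping loop.
#'
#' @param system an `ode_system`.
#' @param y0 initial state.
#' @param t0,t_end integration interval.
#' @param h step size (> 0).
#' @param method `"prototype"`, `"efa"`, `"efb"`, `"efc"` or `"rk6"`.
#' @param omega fitting frequency (rad/time); ignored by `"prototype"`
#'   and `"rk6"`.
#' @param thin store every `thin`-th state (the final grid must be a
#'   multiple; used to align a fine reference run with a coarse grid).
#' @return An `eftdrk_trajectory` with the time grid, states, and exact
#'   function-evaluation counts.
#' @examples
#' sys <- two_gene_system()
#' tr <- integrate_fixed(sys, c(0.6, 0.8, 0.4, 0.6), 0, 10, 1 / 4)
#' tr$eval_counts  # 40 f-evaluations, 160 g-evaluations
#' @export
integrate_fixed <- function(system, y0, t0, t_end, h,
                            method = c("prototype", "efa", "efb", "efc", "rk6"),
                            omega = 0, thin = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(system, "ode_system"), t_end >= t0, h > 0, omega >= 0,
            length(y0) == system$dim)
  n <- .resolve_step_count(t0, t_end, h)
  if (n == 0L) {
    states <- matrix(y0, nrow = 1)
    return(.new_trajectory(t0, states, system, method, h, omega, 0,
                           0L, 0L, NA_character_))
  }
  if (n %% thin != 0L) stop("step count is not a multiple of thin")
  times <- t0 + h * seq(0L, n, by = as.integer(thin))

  if (method == "rk6") {
    tab <- rk6_baseline_tableau()
    if (!is.na(system$compiled_id)) {
      res <- .integrate_rk_cpp(system$compiled_id, system$par_vector, y0,
                               h, n, as.integer(thin), tab$c, tab$A, tab$b)
      if (res$status != 0)
        stop(sprintf("integration failed at t = %g", t0 + h * res$step))
      return(.new_trajectory(times, res$states, system, method, h, omega, 0,
                             as.integer(res$n_f), 0L, NA_character_))
    }
    states <- matrix(NA_real_, n %/% thin + 1L, system$dim)
    states[1, ] <- y <- y0
    for (step in seq_len(n)) {
      y <- tryCatch(.rk_step(system, y, h, tab), error = function(e)
        stop(sprintf("integration failed at t = %g: %s",
                     t0 + h * step, conditionMessage(e)), call. = FALSE))
      if (step %% thin == 0L) states[step %/% thin + 1L, ] <- y
    }
    return(.new_trajectory(times, states, system, method, h, omega, 0,
                           7L * n, 0L, NA_character_))
  }

  nu <- if (method == "prototype") 0 else omega * h
  w <- fitted_weights(method, nu)
  tab <- limit_tableau()

  if (!is.na(system$compiled_id)) {
    res <- .integrate_tdrk_cpp(system$compiled_id, system$par_vector, y0,
                               h, n, as.integer(thin), tab$c, tab$A,
                               w$eta, w$beta, w$b)
    if (res$status != 0)
      stop(sprintf("integration failed at t = %g (stage %s)",
                   t0 + h * res$step, res$stage))
    return(.new_trajectory(times, res$states, system, method, h, omega, nu,
                           res$n_f, res$n_g, w$source))
  }
  states <- matrix(NA_real_, n %/% thin + 1L, system$dim)
  states[1, ] <- y <- y0
  for (step in seq_len(n)) {
    y <- tryCatch(tdrk_step(system, y, h, tab, w), error = function(e)
      stop(sprintf("integration failed at t = %g: %s",
                   t0 + h * step, conditionMessage(e)), call. = FALSE))
    if (step %% thin == 0L) states[step %/% thin + 1L, ] <- y
  }
  .new_trajectory(times, states, system, method, h, omega, nu,
                  n, 4L * n, w$source)
}

#' Write a trajectory to CSV with a JSON sidecar
#'
#' The CSV has columns `time` followed by the model's state names; the
#' sidecar `<file>.json` records method, step size, fitting frequency and
#' evaluation counts for reproducibility.
#'
#' @param traj an `eftdrk_trajectory`.
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(traj, file) {
  stopifnot(inherits(traj, "eftdrk_trajectory"))
  df <- data.frame(time = traj$times, traj$states, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  meta <- list(model = traj$model, method = traj$method, h = traj$h,
               omega = traj$omega, nu = traj$nu,
               n_f = traj$eval_counts$n_f, n_g = traj$eval_counts$n_g)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}
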