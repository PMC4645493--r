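# Steady states, linearisation, oscillation frequencies, global-error
# studies and best-fitting-frequency searches.

#' Damped Newton search for a steady state, with eigen-analysis
#'
#' Solves `f(y) = 0` by Newton iteration with the analytic Jacobian,
#' globalised by backtracking (up to 30 step halvings under an Armijo
#' decrease test on the residual 2-norm) and by projection onto the
#' positive orthant, which is invariant for these concentration models
#' and contains the root.  On convergence the Jacobian at the root is
#' diagonalised: the steady state is flagged oscillatory if some
#' eigenvalue has nonzero imaginary part, and the linearisation
#' frequency is the largest imaginary part in magnitude.
#'
#' @param system an `ode_system`.
#' @param guess strictly positive starting state.
#' @param tol convergence tolerance on the max-norm of `f` (default 1e-12).
#' @param max_iter maximum Newton iterations.
#' @return A `steady_state_report`: `y_star`, `residual_norm`,
#'   `eigenvalues` (complex), `oscillatory`, `linear_frequency`,
#'   `iterations`, `converged`.
#' @examples
#' find_steady_state(two_gene_system(), c(0.5, 0.5, 0.5, 0.5))
#' @export
find_steady_state <- function(system, guess, tol = 1e-12, max_iter = 100L) {
  stopifnot(inherits(system, "ode_system"), all(guess > 0),
            length(guess) == system$dim)
  y <- as.numeric(guess)
  fy <- system$f(y)
  merit <- sqrt(sum(fy^2))
  iter <- 0L
  converged <- max(abs(fy)) < tol
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    J <- system$jac(y)
    delta <- tryCatch(solve(J, fy), error = function(e)
      stop(sprintf("singular Jacobian at iteration %d (residual %.3g)",
                   iter, merit), call. = FALSE))
    step <- 1
    accepted <- FALSE
    for (halve in 0:30) {
      y_new <- pmax(y - step * delta, 1e-8)
      f_new <- system$f(y_new)
      if (all(is.finite(f_new)) &&
          sqrt(sum(f_new^2)) < (1 - 1e-4 * step) * merit) {
        y <- y_new; fy <- f_new; merit <- sqrt(sum(f_new^2))
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted)
      stop(sprintf(
        "Newton iteration stalled at residual %.3g after %d iterations",
        merit, iter))
    converged <- max(abs(fy)) < tol
  }
  if (!converged)
    stop(sprintf("no convergence after %d iterations (residual %.3g)",
                 max_iter, merit))
  res <- max(abs(fy))
  ev <- eigen(system$jac(y), only.values = TRUE)$values
  structure(list(
    y_star = stats::setNames(y, system$state_names),
    residual_norm = res,
    eigenvalues = ev,
    oscillatory = any(abs(Im(ev)) > 0),
    linear_frequency = max(abs(Im(ev))),
    iterations = iter,
    converged = TRUE
  ), class = "steady_state_report")
}

#' @export
print.steady_state_report <- function(x, ...) {
  cat("steady state (residual", format(x$residual_norm, digits = 3), "):\n")
  print(round(x$y_star, 6))
  cat("eigenvalues:\n")
  print(round(x$eigenvalues, 6))
  cat(sprintf("oscillatory: %s, linearisation frequency %.6f\n",
              x$oscillatory, x$linear_frequency))
  invisible(x)
}

#' Limit-cycle angular frequency from interpolated peak times
#'
#' Integrates the system with a fine fixed step, discards the transient,
#' locates strict local maxima of the chosen component and refines each
#' peak time by three-point quadratic interpolation.  The angular
#' frequency is `2 pi` over the mean peak-to-peak interval; the standard
#' deviation of the intervals is returned as a quality metric, and the
#' run is flagged unreliable if it exceeds `1e-3` of the mean.
#'
#' @param system an `ode_system`.
#' @param y0 initial state.
#' @param burn_in transient duration to discard (model time units).
#' @param window measurement window after the transient.
#' @param h integration step size.
#' @param component state index (or name) whose maxima are tracked.
#' @param method,omega integration method for the sampling run.
#' @return A list: `omega` (rad/time), `period`, `n_peaks`,
#'   `interval_sd`, `reliable`.
#' @examples
#' \donttest{
#' limit_cycle_frequency(two_gene_system(), c(0.6, 0.8, 0.4, 0.6),
#'                       burn_in = 200, window = 200, h = 0.005,
#'                       component = "p1")
#' }
#' @export
limit_cycle_frequency <- function(system, y0, burn_in, window, h,
                                  component, method = "prototype",
                                  omega = 0) {
  stopifnot(burn_in >= 0, window > 0, h > 0)
  traj <- integrate_fixed(system, y0, 0, burn_in + window, h,
                          method = method, omega = omega)
  comp <- if (is.character(component))
    match(component, system$state_names) else as.integer(component)
  if (is.na(comp) || comp < 1L || comp > system$dim)
    stop("unknown state component")
  x <- traj$states[, comp]
  tt <- traj$times
  n <- length(x)
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  idx <- idx[tt[idx] > burn_in]
  if (length(idx) < 3L)
    stop("no sustained oscillation detected (fewer than 3 maxima in window)")
  # quadratic refinement of each peak time
  denom <- x[idx - 1L] - 2 * x[idx] + x[idx + 1L]
  delta <- ifelse(denom < 0, 0.5 * (x[idx - 1L] - x[idx + 1L]) / denom, 0)
  peaks <- tt[idx] + delta * h
  intervals <- diff(peaks)
  m <- mean(intervals)
  s <- stats::sd(intervals)
  list(omega = 2 * pi / m, period = m, n_peaks = length(peaks),
       interval_sd = s, reliable = s <= 1e-3 * m)
}

# reference trajectory stored only at the coarse grid points: the
# prototype method at h_ref = min(h/256, 1/1024) by default
.reference_states <- function(system, y0, t0, t_end, h, reference_spec) {
  ref_method <- reference_spec$method %||% "prototype"
  h_ref <- reference_spec$h_ref %||% min(h / 256, 1 / 1024)
  ref_omega <- reference_spec$omega %||% 0
  thin <- round(h / h_ref)
  if (abs(thin * h_ref - h) > 1e-9 * h_ref)
    stop("reference step must divide the coarse step")
  integrate_fixed(system, y0, t0, t_end, h_ref, method = ref_method,
                  omega = ref_omega, thin = thin)$states
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Global error of one fixed-step run against a fine reference
#'
#' The global error (GE) is the absolute deviation of one named state
#' component from a reference solution at the end of the integration
#' interval -- the error accumulated over the whole run.  (The maximum
#' deviation over all grid points is also returned, as `ge_max`.)  The
#' default reference is the prototype TDRK4s6 run at
#' `h_ref = min(h/256, 1/1024)`, compared only at the coarse grid's
#' times; its truncation error sits far below the coarse-run error
#' floor, so the reported GE digits are attributable to the method under
#' test.
#'
#' @param system an `ode_system`.
#' @param y0 initial state.
#' @param t0,t_end integration interval.
#' @param h coarse step size.
#' @param method,omega method under test and its fitting frequency.
#' @param component state index or name whose error is measured.
#' @param reference_spec list with optional fields `method`, `h_ref`,
#'   `omega` overriding the reference run; `h_ref = h` with the same
#'   method reproduces the run itself (GE 0).
#' @return A `global_error_result`: `model`, `method`, `h`, `omega`,
#'   `component`, `ge`, `n_f`, `n_g`.
#' @examples
#' \donttest{
#' global_error(two_gene_system(), c(0.6, 0.8, 0.4, 0.6), 0, 100, 1 / 4,
#'              method = "prototype", component = "p1")
#' }
#' @export
global_error <- function(system, y0, t0, t_end, h, method = "prototype",
                         omega = 0, component = 1L,
                         reference_spec = list()) {
  comp <- if (is.character(component))
    match(component, system$state_names) else as.integer(component)
  if (is.na(comp) || comp < 1L || comp > system$dim)
    stop("unknown state component")
  ref <- .reference_states(system, y0, t0, t_end, h, reference_spec)
  traj <- integrate_fixed(system, y0, t0, t_end, h, method = method,
                          omega = omega)
  err <- abs(traj$states[, comp] - ref[, comp])
  structure(list(model = system$name, method = method, h = h, omega = omega,
                 component = system$state_names[comp],
                 ge = err[length(err)], ge_max = max(err),
                 n_f = traj$eval_counts$n_f, n_g = traj$eval_counts$n_g),
            class = "global_error_result")
}

#' @export
print.global_error_result <- function(x, ...) {
  cat(sprintf("GE(%s) = %.4e  [model %s, method %s, h = %g, omega = %g]\n",
              x$component, x$ge, x$model, x$method, x$h, x$omega))
  invisible(x)
}

#' Grid search for the best fitting frequency
#'
#' Evaluates the global error as a function of the fitting frequency
#' `omega` on a grid (default: 0 to `min(pi/h, 4)` in steps of 0.001,
#' matching the 3-decimal resolution of reported best frequencies) and
#' returns the minimiser.  Ties resolve to the smallest `omega`.  The
#' reference trajectory is computed once and shared across the grid.
#'
#' @param system an `ode_system`.
#' @param y0 initial state.
#' @param t0,t_end integration interval.
#' @param h step size.
#' @param method fitted method whose frequency is searched.
#' @param component state component whose GE is minimised.
#' @param omega_grid increasing numeric grid of candidate frequencies.
#' @param reference_spec optional reference override as in
#'   [global_error()].
#' @return A list: `omega_star`, `ge_star`, and `profile`, a data frame
#'   of `(omega, ge)` over the grid (failed grid points carry `NA` and
#'   are excluded from the minimisation with a warning).
#' @examples
#' \donttest{
#' best_fitting_frequency(per_circadian_system(),
#'   c(0.1, 0.25, 0.25, 0.25, 0.25), 0, 100, 1 / 2,
#'   method = "efa", component = "PN")
#' }
#' @export
best_fitting_frequency <- function(system, y0, t0, t_end, h, method,
                                   component,
                                   omega_grid = NULL,
                                   reference_spec = list()) {
  if (is.null(omega_grid))
    omega_grid <- seq(0, min(pi / h, 4), by = 0.001)
  stopifnot(!is.unsorted(omega_grid), length(omega_grid) >= 1L)
  comp <- if (is.character(component))
    match(component, system$state_names) else as.integer(component)
  if (is.na(comp) || comp < 1L || comp > system$dim)
    stop("unknown state component")
  ref <- .reference_states(system, y0, t0, t_end, h, reference_spec)
  ref_end <- ref[nrow(ref), comp]
  n <- .resolve_step_count(t0, t_end, h)
  ge <- vapply(omega_grid, function(om) {
    tr <- tryCatch(
      suppressWarnings(integrate_fixed(system, y0, t0, t_end, h,
                                       method = method, omega = om,
                                       thin = n)),
      error = function(e) NULL)
    if (is.null(tr)) return(NA_real_)
    abs(tr$states[nrow(tr$states), comp] - ref_end)
  }, numeric(1))
  if (anyNA(ge))
    warning(sprintf("%d grid points failed to integrate and were excluded",
                    sum(is.na(ge))))
  if (all(is.na(ge))) stop("integration failed on the whole frequency grid")
  i <- which.min(ge)  # ties resolve to the smallest omega
  list(omega_star = omega_grid[i], ge_star = ge[i],
       profile = data.frame(omega = omega_grid, ge = ge))
}

#' Accuracy-versus-cost table for a set of methods and step sizes
#'
#' One row per (method, step size): the total number of function
#' evaluations (`n_f + n_g`) and the global error, the data behind
#' efficiency curves.
#'
#' @param system an `ode_system`.
#' @param y0 initial state.
#' @param t0,t_end integration interval.
#' @param h_list step sizes.
#' @param methods data frame with columns `method` and `omega` (one row
#'   per method; `omega` is ignored by `prototype` and `rk6`).
#' @param component state component for the global error.
#' @param reference_spec optional reference override.
#' @return A data frame with columns `method`, `h`, `omega`, `n_f`,
#'   `n_g`, `n_evals`, `ge`.
#' @export
efficiency_table <- function(system, y0, t0, t_end, h_list, methods,
                             component, reference_spec = list()) {
  stopifnot(is.data.frame(methods), "method" %in% names(methods))
  if (is.null(methods$omega)) methods$omega <- 0
  rows <- list()
  for (h in h_list) {
    for (r in seq_len(nrow(methods))) {
      res <- global_error(system, y0, t0, t_end, h,
                          method = methods$method[r],
                          omega = methods$omega[r],
                          component = component,
                          reference_spec = reference_spec)
      rows[[length(rows) + 1L]] <- data.frame(
        method = res$method, h = h, omega = res$omega,
        n_f = res$n_f, n_g = res$n_g, n_evals = res$n_f + res$n_g,
        ge = res$ge)
    }
  }
  do.call(rbind, rows)
}
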