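# Benchmark genetic-oscillator ODE systems.
#
# Every model is packaged as an `ode_system`: dimension, vector field f,
# analytic Jacobian J, and the second-derivative field g(y) = J(y) f(y)
# that two-derivative integrators evaluate at the stages.  g is always
# computed as J f from the analytic Jacobian rather than from a separately
# transcribed closed form, so a single source of truth feeds both the
# steppers and the steady-state analysis; closed forms and finite
# differences serve as independent oracles in the tests.

#' Hill regulation function
#'
#' Sigmoidal transcriptional response `p^n / (p^n + theta^n)` (activation)
#' or its complement `theta^n / (p^n + theta^n)` (inhibition).  At `p = 0`
#' activation returns 0 (the limit convention, avoiding `0^n/0`).
#'
#' @param kind `"activation"` or `"inhibition"`.
#' @param p protein concentration, `>= 0` (vectorised).
#' @param theta threshold concentration, `> 0`.
#' @param n Hill coefficient, `> 0`.
#' @return Values in `[0, 1]`.
#' @examples
#' hill("activation", 0.21, 0.21, 3)  # 1/2 at the threshold
#' @export
hill <- function(kind = c("activation", "inhibition"), p, theta, n) {
  kind <- match.arg(kind)
  if (any(p < 0)) stop("hill(): negative concentration")
  stopifnot(theta > 0, n > 0)
  pn <- p^n
  tn <- theta^n
  if (kind == "activation") pn / (pn + tn) else tn / (pn + tn)
}

.new_ode_system <- function(name, dim, f, jac, state_names, params,
                            compiled_id = NA_integer_, par_vector = NULL) {
  g <- function(y) as.vector(jac(y) %*% f(y))
  structure(list(name = name, dim = dim, f = f, jac = jac, g = g,
                 state_names = state_names, params = params,
                 compiled_id = compiled_id, par_vector = par_vector),
            class = "ode_system")
}

#' @export
print.ode_system <- function(x, ...) {
  cat(sprintf("ode_system '%s', dimension %d, states: %s\n",
              x$name, x$dim, paste(x$state_names, collapse = ", ")))
  invisible(x)
}

.check_positive <- function(params) {
  bad <- names(params)[!vapply(params, function(v) is.numeric(v) && v > 0,
                               logical(1))]
  if (length(bad))
    stop("parameters must be strictly positive: ", paste(bad, collapse = ", "))
  params
}

#' Parameters of the two-gene cross-regulation model
#'
#' Defaults are the benchmark values: Hill coefficients 3, maximal
#' transcription rates 1.15 and 2.35, unit degradation and translation
#' rates, thresholds 0.21.  Gene 1 is activated by protein 2; gene 2 is
#' inhibited by protein 1.
#'
#' @param n1,n2 Hill coefficients (dimensionless).
#' @param lambda1,lambda2 maximal transcription rates (conc/time).
#' @param gamma1,gamma2 mRNA degradation rates (1/time).
#' @param kappa1,kappa2 translation rates (1/time).
#' @param mu1,mu2 protein degradation rates (1/time).
#' @param theta1,theta2 regulation thresholds (conc).
#' @return A named list of validated (strictly positive) parameters.
#' @export
two_gene_params <- function(n1 = 3, n2 = 3, lambda1 = 1.15, lambda2 = 2.35,
                            gamma1 = 1, gamma2 = 1, kappa1 = 1, kappa2 = 1,
                            mu1 = 1, mu2 = 1, theta1 = 0.21, theta2 = 0.21) {
  .check_positive(list(n1 = n1, n2 = n2, lambda1 = lambda1, lambda2 = lambda2,
                       gamma1 = gamma1, gamma2 = gamma2, kappa1 = kappa1,
                       kappa2 = kappa2, mu1 = mu1, mu2 = mu2,
                       theta1 = theta1, theta2 = theta2))
}

#' The two-gene cross-regulation system
#'
#' Four ODEs for mRNA and protein concentrations `(m1, m2, p1, p2)`:
#' protein 2 activates transcription of gene 1 and protein 1 inhibits
#' gene 2, both through Hill functions, with linear translation and
#' first-order degradation.  With the default parameters the unique
#' positive steady state is linearly unstable with a complex eigenvalue
#' pair, and trajectories settle on a limit cycle.
#'
#' @param params a list from [two_gene_params()].
#' @return An `ode_system` of dimension 4 with analytic Jacobian and
#'   `g = J f`.
#' @examples
#' sys <- two_gene_system()
#' sys$f(c(0.6, 0.8, 0.4, 0.6))
#' @export
two_gene_system <- function(params = two_gene_params()) {
  p <- params
  jac <- function(y) {
    p1 <- y[3]; p2 <- y[4]
    d1 <- p$theta1^p$n1 + p1^p$n1
    d2 <- p$theta2^p$n2 + p2^p$n2
    matrix(c(
      -p$gamma1, 0, 0, p$lambda1 * p$n2 * p$theta2^p$n2 * p2^(p$n2 - 1) / d2^2,
      0, -p$gamma2, -p$lambda2 * p$n1 * p$theta1^p$n1 * p1^(p$n1 - 1) / d1^2, 0,
      p$kappa1, 0, -p$mu1, 0,
      0, p$kappa2, 0, -p$mu2
    ), nrow = 4, byrow = TRUE)
  }
  # f allows transiently negative concentrations at coarse steps: the Hill
  # terms stay defined because the defaults have integer Hill coefficients
  fr <- function(y) {
    p1 <- y[3]; p2 <- y[4]
    c(p$lambda1 * p2^p$n2 / (p2^p$n2 + p$theta2^p$n2) - p$gamma1 * y[1],
      p$lambda2 * p$theta1^p$n1 / (p1^p$n1 + p$theta1^p$n1) - p$gamma2 * y[2],
      p$kappa1 * y[1] - p$mu1 * y[3],
      p$kappa2 * y[2] - p$mu2 * y[4])
  }
  .new_ode_system("two_gene", 4L, fr, jac,
                  c("m1", "m2", "p1", "p2"), p,
                  compiled_id = 1L,
                  par_vector = unlist(p[c("n1", "n2", "lambda1", "lambda2",
                                          "gamma1", "gamma2", "kappa1",
                                          "kappa2", "mu1", "mu2",
                                          "theta1", "theta2")]))
}

#' Parameters of the PER circadian oscillation model
#'
#' Defaults are the benchmark values for the five-variable model of PER
#' protein oscillations in Drosophila: mRNA synthesis repressed by
#' nuclear PER through a Hill term (`vs`, `KI`, `n`), Michaelian mRNA
#' degradation (`vm`, `Km1`), translation (`ks`), reversible
#' phosphorylation between three PER states (`V1..V4`, `K1..K4`),
#' nuclear shuttling (`k1`, `k2`) and degradation of fully
#' phosphorylated PER (`vd`, `Kd`).  Rates are in uM/h or 1/h,
#' concentrations in uM.
#'
#' @param vs,vm,ks,vd,k1,k2,KI,Kd,Km1,K1,K2,K3,K4,n,V1,V2,V3,V4
#'   model constants, all strictly positive.
#' @return A named list of validated parameters.
#' @export
per_params <- function(vs = 0.76, vm = 0.65, ks = 0.38, vd = 0.95,
                       k1 = 1.9, k2 = 1.3, KI = 1, Kd = 0.2, Km1 = 0.5,
                       K1 = 2, K2 = 2, K3 = 2, K4 = 2, n = 4,
                       V1 = 3.2, V2 = 1.58, V3 = 5, V4 = 2.5) {
  .check_positive(list(vs = vs, vm = vm, ks = ks, vd = vd, k1 = k1, k2 = k2,
                       KI = KI, Kd = Kd, Km1 = Km1, K1 = K1, K2 = K2,
                       K3 = K3, K4 = K4, n = n, V1 = V1, V2 = V2, V3 = V3,
                       V4 = V4))
}

#' The five-variable PER circadian oscillator
#'
#' Goldbeter's model of circadian PER oscillations in Drosophila: state
#' `(M, P0, P1, P2, PN)` = cytosolic per mRNA, un-, mono- and
#' bis-phosphorylated PER, and nuclear PER.  Nuclear PER represses
#' transcription through a Hill term; all enzymatic steps are Michaelian.
#' The Jacobian is derived analytically from the Michaelis-Menten and
#' Hill partial derivatives.
#'
#' @param params a list from [per_params()].
#' @return An `ode_system` of dimension 5.
#' @examples
#' sys <- per_circadian_system()
#' sys$f(c(0.1, 0.25, 0.25, 0.25, 0.25))
#' @export
per_circadian_system <- function(params = per_params()) {
  p <- params
  f <- function(y) {
    M <- y[1]; P0 <- y[2]; P1 <- y[3]; P2 <- y[4]; PN <- y[5]
    U <- p$V1 * P0 / (p$K1 + P0)
    B <- p$V2 * P1 / (p$K2 + P1)
    C <- p$V3 * P1 / (p$K3 + P1)
    D <- p$V4 * P2 / (p$K4 + P2)
    E <- p$vd * P2 / (p$Kd + P2)
    KIn <- p$KI^p$n
    c(p$vs * KIn / (KIn + PN^p$n) - p$vm * M / (p$Km1 + M),
      p$ks * M - U + B,
      U - B - C + D,
      C - D - p$k1 * P2 + p$k2 * PN - E,
      p$k1 * P2 - p$k2 * PN)
  }
  jac <- function(y) {
    M <- y[1]; P0 <- y[2]; P1 <- y[3]; P2 <- y[4]; PN <- y[5]
    KIn <- p$KI^p$n
    dU <- p$V1 * p$K1 / (p$K1 + P0)^2
    dB <- p$V2 * p$K2 / (p$K2 + P1)^2
    dC <- p$V3 * p$K3 / (p$K3 + P1)^2
    dD <- p$V4 * p$K4 / (p$K4 + P2)^2
    dE <- p$vd * p$Kd / (p$Kd + P2)^2
    dHill <- -p$n * p$vs * KIn * PN^(p$n - 1) / (KIn + PN^p$n)^2
    dM <- -p$vm * p$Km1 / (p$Km1 + M)^2
    matrix(c(
      dM, 0, 0, 0, dHill,
      p$ks, -dU, dB, 0, 0,
      0, dU, -dB - dC, dD, 0,
      0, 0, dC, -dD - p$k1 - dE, p$k2,
      0, 0, 0, p$k1, -p$k2
    ), nrow = 5, byrow = TRUE)
  }
  .new_ode_system("per", 5L, f, jac,
                  c("M", "P0", "P1", "P2", "PN"), p,
                  compiled_id = 2L,
                  par_vector = unlist(p[c("vs", "vm", "ks", "vd", "k1", "k2",
                                          "KI", "Kd", "Km1", "K1", "K2",
                                          "K3", "K4", "n", "V1", "V2",
                                          "V3", "V4")]))
}

#' Assemble a general N-gene regulatory system
#'
#' Builds the 2N-dimensional mRNA/protein system
#' `dm/dt = R(p) - Gamma m`, `dp/dt = kappa m - M p` from a regulation
#' function and its partial derivatives.  State order is
#' `(m_1..m_N, p_1..p_N)`.
#'
#' @param spec a list with fields `N` (gene count), `R` (function of the
#'   protein vector returning N regulation rates), `dRdp` (function
#'   returning the N x N matrix of partials of `R` w.r.t. the proteins),
#'   `kappa`, `gamma`, `mu` (translation and degradation rate vectors,
#'   recycled to length N), and optionally `name`.
#' @return An `ode_system` of dimension `2 N` with block Jacobian
#'   `[[-Gamma, dR/dp], [diag(kappa), -M]]`.
#' @export
n_gene_system <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$N), is.function(spec$R),
            is.function(spec$dRdp))
  N <- as.integer(spec$N)
  kappa <- rep_len(spec$kappa, N)
  gamma <- rep_len(spec$gamma, N)
  mu <- rep_len(spec$mu, N)
  test_R <- spec$R(rep(1, N))
  if (length(test_R) != N) stop("R(p) must return ", N, " values")
  test_J <- spec$dRdp(rep(1, N))
  if (!is.matrix(test_J) || any(dim(test_J) != N))
    stop("dRdp(p) must return an ", N, "x", N, " matrix")
  f <- function(y) {
    m <- y[seq_len(N)]; pp <- y[N + seq_len(N)]
    c(spec$R(pp) - gamma * m, kappa * m - mu * pp)
  }
  jac <- function(y) {
    pp <- y[N + seq_len(N)]
    rbind(cbind(diag(-gamma, N), spec$dRdp(pp)),
          cbind(diag(kappa, N), diag(-mu, N)))
  }
  nm <- if (is.null(spec$name)) sprintf("n_gene_%d", N) else spec$name
  .new_ode_system(nm, 2L * N, f, jac,
                  c(paste0("m", seq_len(N)), paste0("p", seq_len(N))),
                  spec)
}

#' Look up a built-in model by name
#'
#' @param name `"two_gene"` or `"per"`.
#' @param overrides named list of parameter overrides passed to the
#'   model's parameter constructor.
#' @return An `ode_system`.
#' @examples
#' get_model("two_gene", list(lambda1 = 1.2))
#' @export
get_model <- function(name, overrides = list()) {
  switch(name,
    two_gene = two_gene_system(do.call(two_gene_params, overrides)),
    per = per_circadian_system(do.call(per_params, overrides)),
    stop(sprintf("unknown model '%s' (available: two_gene, per)", name)))
}
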