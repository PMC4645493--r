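// Compiled kernels: fixed-step TDRK / RK6 integration loops for the two
// built-in gene-network models, and an extended-precision solve of the
// 6x6 exponential-fitting system (ill-conditioned as nu -> 0).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// built-in models.  Parameter vectors are packed by the R constructors:
//   two_gene: n1 n2 lambda1 lambda2 gamma1 gamma2 kappa1 kappa2 mu1 mu2
//             theta1 theta2                                     (dim 4)
//   per:      vs vm ks vd k1 k2 KI Kd Km1 K1 K2 K3 K4 n V1..V4  (dim 5)

static void two_gene_f(const double* y, const double* p, double* out) {
  const double n1 = p[0], n2 = p[1], l1 = p[2], l2 = p[3], g1 = p[4],
               g2 = p[5], k1 = p[6], k2 = p[7], mu1 = p[8], mu2 = p[9],
               th1 = p[10], th2 = p[11];
  const double p1 = y[2], p2 = y[3];
  const double p1n = std::pow(p1, n1), p2n = std::pow(p2, n2);
  const double t1n = std::pow(th1, n1), t2n = std::pow(th2, n2);
  out[0] = l1 * p2n / (p2n + t2n) - g1 * y[0];
  out[1] = l2 * t1n / (p1n + t1n) - g2 * y[1];
  out[2] = k1 * y[0] - mu1 * y[2];
  out[3] = k2 * y[1] - mu2 * y[3];
}

// g = J(y) f(y), with the analytic Jacobian
static void two_gene_g(const double* y, const double* p, double* out) {
  const double n1 = p[0], n2 = p[1], l1 = p[2], l2 = p[3], g1 = p[4],
               g2 = p[5], k1 = p[6], k2 = p[7], mu1 = p[8], mu2 = p[9],
               th1 = p[10], th2 = p[11];
  const double p1 = y[2], p2 = y[3];
  const double p1n = std::pow(p1, n1), p2n = std::pow(p2, n2);
  const double t1n = std::pow(th1, n1), t2n = std::pow(th2, n2);
  const double d1 = t1n + p1n, d2 = t2n + p2n;
  double f[4];
  f[0] = l1 * p2n / d2 - g1 * y[0];
  f[1] = l2 * t1n / d1 - g2 * y[1];
  f[2] = k1 * y[0] - mu1 * y[2];
  f[3] = k2 * y[1] - mu2 * y[3];
  const double j14 = l1 * n2 * t2n * std::pow(p2, n2 - 1.0) / (d2 * d2);
  const double j23 = -l2 * n1 * t1n * std::pow(p1, n1 - 1.0) / (d1 * d1);
  out[0] = -g1 * f[0] + j14 * f[3];
  out[1] = -g2 * f[1] + j23 * f[2];
  out[2] = k1 * f[0] - mu1 * f[2];
  out[3] = k2 * f[1] - mu2 * f[3];
}

static void per_f(const double* y, const double* p, double* out) {
  const double vs = p[0], vm = p[1], ks = p[2], vd = p[3], k1 = p[4],
               k2 = p[5], KI = p[6], Kd = p[7], Km1 = p[8], K1 = p[9],
               K2 = p[10], K3 = p[11], K4 = p[12], n = p[13], V1 = p[14],
               V2 = p[15], V3 = p[16], V4 = p[17];
  const double M = y[0], P0 = y[1], P1 = y[2], P2 = y[3], PN = y[4];
  const double KIn = std::pow(KI, n), PNn = std::pow(PN, n);
  const double U = V1 * P0 / (K1 + P0), B = V2 * P1 / (K2 + P1);
  const double C = V3 * P1 / (K3 + P1), D = V4 * P2 / (K4 + P2);
  const double E = vd * P2 / (Kd + P2);
  out[0] = vs * KIn / (KIn + PNn) - vm * M / (Km1 + M);
  out[1] = ks * M - U + B;
  out[2] = U - B - C + D;
  out[3] = C - D - k1 * P2 + k2 * PN - E;
  out[4] = k1 * P2 - k2 * PN;
}

static void per_g(const double* y, const double* p, double* out) {
  const double vs = p[0], vm = p[1], ks = p[2], vd = p[3], k1 = p[4],
               k2 = p[5], KI = p[6], Kd = p[7], Km1 = p[8], K1 = p[9],
               K2 = p[10], K3 = p[11], K4 = p[12], n = p[13], V1 = p[14],
               V2 = p[15], V3 = p[16], V4 = p[17];
  const double M = y[0], P0 = y[1], P1 = y[2], P2 = y[3], PN = y[4];
  const double KIn = std::pow(KI, n), PNn = std::pow(PN, n);
  double f[5];
  per_f(y, p, f);
  // Michaelis-Menten partials V K / (K + x)^2 and Hill inhibition partial
  const double dU = V1 * K1 / ((K1 + P0) * (K1 + P0));
  const double dB = V2 * K2 / ((K2 + P1) * (K2 + P1));
  const double dC = V3 * K3 / ((K3 + P1) * (K3 + P1));
  const double dD = V4 * K4 / ((K4 + P2) * (K4 + P2));
  const double dE = vd * Kd / ((Kd + P2) * (Kd + P2));
  const double dHill = -n * vs * KIn * std::pow(PN, n - 1.0) /
                       ((KIn + PNn) * (KIn + PNn));
  const double dM = -vm * Km1 / ((Km1 + M) * (Km1 + M));
  out[0] = dM * f[0] + dHill * f[4];
  out[1] = ks * f[0] - dU * f[1] + dB * f[2];
  out[2] = dU * f[1] + (-dB - dC) * f[2] + dD * f[3];
  out[3] = dC * f[2] + (-dD - k1 - dE) * f[3] + k2 * f[4];
  out[4] = k1 * f[3] - k2 * f[4];
}

typedef void (*model_fun)(const double*, const double*, double*);

static void pick_model(int model_id, model_fun& f, model_fun& g, int& dim) {
  if (model_id == 1) { f = two_gene_f; g = two_gene_g; dim = 4; }
  else if (model_id == 2) { f = per_f; g = per_g; dim = 5; }
  else stop("unknown compiled model id");
}

// ---------------------------------------------------------------------------
// fixed-step TDRK loop.  Per step: 1 f evaluation, 4 g evaluations.
// States are stored every `thin` steps (row 0 = initial state).

// [[Rcpp::export(name = ".integrate_tdrk_cpp")]]
List integrate_tdrk_cpp(int model_id, NumericVector pars, NumericVector y0,
                        double h, int nsteps, int thin,
                        NumericVector cvec, NumericMatrix A,
                        double eta, double beta, NumericVector b) {
  model_fun f = nullptr, g = nullptr;
  int d = 0;
  pick_model(model_id, f, g, d);
  if ((int)y0.size() != d) stop("state dimension mismatch");
  if (nsteps % thin != 0) stop("nsteps must be a multiple of thin");

  const int nout = nsteps / thin + 1;
  NumericMatrix out(nout, d);
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> fy(d), Y(d);
  std::vector< std::vector<double> > gY(4, std::vector<double>(d));
  const double h2 = h * h;
  const double* pp = REAL(pars);

  for (int k = 0; k < d; ++k) out(0, k) = y[k];

  for (int step = 0; step < nsteps; ++step) {
    f(y.data(), pp, fy.data());
    for (int i = 0; i < 4; ++i) {
      for (int k = 0; k < d; ++k) {
        double acc = y[k] + cvec[i] * h * fy[k];
        for (int j = 0; j < i; ++j)
          if (A(i, j) != 0.0) acc += h2 * A(i, j) * gY[j][k];
        Y[k] = acc;
      }
      g(Y.data(), pp, gY[i].data());
      for (int k = 0; k < d; ++k)
        if (!std::isfinite(gY[i][k]))
          return List::create(_["status"] = 1, _["step"] = step + 1,
                              _["stage"] = i + 1);
    }
    bool ok = true;
    for (int k = 0; k < d; ++k) {
      y[k] = eta * y[k] + h * beta * fy[k] +
             h2 * (b[0] * gY[0][k] + b[1] * gY[1][k] +
                   b[2] * gY[2][k] + b[3] * gY[3][k]);
      if (!std::isfinite(y[k])) ok = false;
    }
    if (!ok)
      return List::create(_["status"] = 1, _["step"] = step + 1,
                          _["stage"] = NA_INTEGER);
    if ((step + 1) % thin == 0) {
      const int row = (step + 1) / thin;
      for (int k = 0; k < d; ++k) out(row, k) = y[k];
    }
  }
  return List::create(_["status"] = 0, _["states"] = out,
                      _["n_f"] = nsteps, _["n_g"] = 4 * nsteps);
}

// ---------------------------------------------------------------------------
// classical explicit RK loop (any tableau; used for the 7-stage order-6
// baseline).  Per step: s f evaluations.

// [[Rcpp::export(name = ".integrate_rk_cpp")]]
List integrate_rk_cpp(int model_id, NumericVector pars, NumericVector y0,
                      double h, int nsteps, int thin,
                      NumericVector cvec, NumericMatrix A, NumericVector b) {
  model_fun f = nullptr, g = nullptr;
  int d = 0;
  pick_model(model_id, f, g, d);
  if ((int)y0.size() != d) stop("state dimension mismatch");
  if (nsteps % thin != 0) stop("nsteps must be a multiple of thin");
  const int s = cvec.size();

  const int nout = nsteps / thin + 1;
  NumericMatrix out(nout, d);
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> Y(d);
  std::vector< std::vector<double> > K(s, std::vector<double>(d));

  for (int k = 0; k < d; ++k) out(0, k) = y[k];

  for (int step = 0; step < nsteps; ++step) {
    for (int i = 0; i < s; ++i) {
      for (int k = 0; k < d; ++k) {
        double acc = y[k];
        for (int j = 0; j < i; ++j)
          if (A(i, j) != 0.0) acc += h * A(i, j) * K[j][k];
        Y[k] = acc;
      }
      f(Y.data(), REAL(pars), K[i].data());
    }
    bool ok = true;
    for (int k = 0; k < d; ++k) {
      double acc = 0.0;
      for (int i = 0; i < s; ++i) acc += b[i] * K[i][k];
      y[k] += h * acc;
      if (!std::isfinite(y[k])) ok = false;
    }
    if (!ok)
      return List::create(_["status"] = 1, _["step"] = step + 1,
                          _["stage"] = NA_INTEGER);
    if ((step + 1) % thin == 0) {
      const int row = (step + 1) / thin;
      for (int k = 0; k < d; ++k) out(row, k) = y[k];
    }
  }
  return List::create(_["status"] = 0, _["states"] = out,
                      _["n_f"] = (double)nsteps * s, _["n_g"] = 0);
}

// ---------------------------------------------------------------------------
// extended-precision solve of the 6x6 exponential-fitting system for
// method a.  The matrix condition number grows like nu^-3, so a plain
// double solve loses digits near the series switch point; Gaussian
// elimination in long double plus one step of iterative refinement keeps
// the weights accurate to near double precision.

static bool lu_solve_ld(long double M[6][6], long double x[6],
                        const long double rhs[6]) {
  long double a[6][7];
  for (int i = 0; i < 6; ++i) {
    for (int j = 0; j < 6; ++j) a[i][j] = M[i][j];
    a[i][6] = rhs[i];
  }
  for (int col = 0; col < 6; ++col) {
    int piv = col;
    for (int r = col + 1; r < 6; ++r)
      if (fabsl(a[r][col]) > fabsl(a[piv][col])) piv = r;
    if (a[piv][col] == 0.0L) return false;
    if (piv != col)
      for (int j = col; j < 7; ++j) std::swap(a[piv][j], a[col][j]);
    for (int r = col + 1; r < 6; ++r) {
      const long double m = a[r][col] / a[col][col];
      for (int j = col; j < 7; ++j) a[r][j] -= m * a[col][j];
    }
  }
  for (int i = 5; i >= 0; --i) {
    long double s = a[i][6];
    for (int j = i + 1; j < 6; ++j) s -= a[i][j] * x[j];
    x[i] = s / a[i][i];
  }
  return true;
}

// [[Rcpp::export(name = ".solve_weights_a_cpp")]]
NumericVector solve_weights_a_cpp(double nu_) {
  const long double nu = (long double)nu_;
  const long double cc[4] = {0.0L, 0.25L, 2.0L / 3.0L, 1.0L};
  long double s[4], co[4];
  for (int i = 0; i < 4; ++i) { s[i] = sinl(cc[i] * nu); co[i] = cosl(cc[i] * nu); }
  long double M[6][6] = {
    {0, -nu, 0, nu * nu * s[1], nu * nu * s[2], nu * nu * s[3]},
    {-1, 0, nu * nu, nu * nu * co[1], nu * nu * co[2], nu * nu * co[3]},
    {0, -1, 0,
     nu * nu * cc[1] * co[1] + 2 * nu * s[1],
     nu * nu * cc[2] * co[2] + 2 * nu * s[2],
     nu * nu * cc[3] * co[3] + 2 * nu * s[3]},
    {0, 0, 2 * nu,
     2 * nu * co[1] - nu * nu * cc[1] * s[1],
     2 * nu * co[2] - nu * nu * cc[2] * s[2],
     2 * nu * co[3] - nu * nu * cc[3] * s[3]},
    {0, 0, 1, 1, 1, 1},
    {0, 0, 0, cc[1], cc[2], cc[3]}
  };
  long double rhs[6] = {-sinl(nu), -cosl(nu), -cosl(nu), sinl(nu),
                        0.5L, 1.0L / 6.0L};
  long double x[6];
  if (!lu_solve_ld(M, x, rhs)) {
    NumericVector bad(6, NA_REAL);
    return bad;
  }
  // one refinement pass: residual and correction in long double
  long double r[6], dx[6];
  for (int i = 0; i < 6; ++i) {
    long double acc = rhs[i];
    for (int j = 0; j < 6; ++j) acc -= M[i][j] * x[j];
    r[i] = acc;
  }
  if (lu_solve_ld(M, dx, r))
    for (int i = 0; i < 6; ++i) x[i] += dx[i];
  NumericVector out(6);
  for (int i = 0; i < 6; ++i) out[i] = (double)x[i];
  return out;
}
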