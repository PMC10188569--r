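#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// log-sum-exp of eta, and in-place refresh of q = exp(eta - logZ)
static double refresh_q(const std::vector<double>& eta, std::vector<double>& q) {
  const int n = (int)eta.size();
  double mx = eta[0];
  for (int i = 1; i < n; ++i) if (eta[i] > mx) mx = eta[i];
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::exp(eta[i] - mx);
  double logZ = mx + std::log(s);
  for (int i = 0; i < n; ++i) q[i] = std::exp(eta[i] - logZ);
  return logZ;
}

// Cyclic coordinate descent with soft-thresholding for the L1-penalized
// maxent objective
//   f(lambda) = -pbar'lambda + log Z(lambda) + sum_j beta_j |lambda_j|
// where Z = sum over background rows of exp(F lambda).
// Each coordinate takes a damped Newton step on the smooth part followed by
// the L1 proximal map; a step-halving backtrack guarantees monotone descent.
// [[Rcpp::export]]
List maxent_cd(NumericMatrix F, NumericVector pbar, NumericVector beta,
               int max_iter, double tol, double accept_tol = 1e-12) {
  const int N = F.nrow(), J = F.ncol();
  std::vector<double> eta(N, 0.0), q(N, 1.0 / N);
  std::vector<double> lambda(J, 0.0);
  double logZ = std::log((double)N);
  const double logN = logZ;

  // objective pieces tracked incrementally
  double lin = 0.0;   // pbar'lambda
  double pen = 0.0;   // sum beta |lambda|
  double f = -lin + logZ + pen;

  std::vector<int> tr_feat; std::vector<double> tr_gain;
  tr_feat.reserve(256); tr_gain.reserve(256);

  int sweeps = 0;
  bool converged = false;

  for (int it = 0; it < max_iter; ++it) {
    double f_sweep_start = f;
    for (int j = 0; j < J; ++j) {
      const double* col = &F(0, j);
      double Eq = 0.0, Eq2 = 0.0;
      for (int i = 0; i < N; ++i) { double v = col[i] * q[i]; Eq += v; Eq2 += v * col[i]; }
      double g = -pbar[j] + Eq;
      double h = Eq2 - Eq * Eq;
      if (h < 1e-10) h = 1e-10;
      double z = lambda[j] - g / h;
      double az = std::fabs(z) - beta[j] / h;
      double lnew = (az > 0.0) ? ((z > 0) - (z < 0)) * az : 0.0;
      double delta = lnew - lambda[j];
      if (std::fabs(delta) < 1e-12) continue;

      // backtracking on the true objective
      bool accepted = false;
      for (int bt = 0; bt < 40; ++bt) {
        double lj = lambda[j] + delta;
        // candidate eta / logZ
        double mx = -INFINITY;
        for (int i = 0; i < N; ++i) {
          double e = eta[i] + delta * col[i];
          if (e > mx) mx = e;
        }
        double s = 0.0;
        for (int i = 0; i < N; ++i) s += std::exp(eta[i] + delta * col[i] - mx);
        double logZ_c = mx + std::log(s);
        double lin_c = lin + delta * pbar[j];
        double pen_c = pen - beta[j] * std::fabs(lambda[j]) + beta[j] * std::fabs(lj);
        double f_c = -lin_c + logZ_c + pen_c;
        if (!std::isfinite(f_c))
          stop("non-finite objective during fitting; check feature scaling");
        if (f_c <= f + accept_tol) {
          for (int i = 0; i < N; ++i) eta[i] += delta * col[i];
          lambda[j] = lj; lin = lin_c; pen = pen_c; logZ = logZ_c;
          if (f_c < f) { // record only genuine improvements in the trace
            tr_feat.push_back(j + 1);
            tr_gain.push_back(logN - f_c);
          }
          f = f_c;
          refresh_q(eta, q);
          accepted = true;
          break;
        }
        delta *= 0.5;
        if (std::fabs(delta) < 1e-14) break;
      }
      (void)accepted;
    }
    sweeps = it + 1;
    if (f_sweep_start - f < tol) { converged = true; break; }
  }

  return List::create(
    _["lambda"] = NumericVector(lambda.begin(), lambda.end()),
    _["objective"] = f,
    _["logZ"] = logZ,
    _["eta"] = NumericVector(eta.begin(), eta.end()),
    _["gain"] = logN - f,
    _["iterations"] = sweeps,
    _["converged"] = converged,
    _["trace_feature"] = IntegerVector(tr_feat.begin(), tr_feat.end()),
    _["trace_gain"] = NumericVector(tr_gain.begin(), tr_gain.end()));
}
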