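#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Exact weighted 1-D fused lasso
//   min_theta 0.5 * sum w_i (theta_i - z_i)^2 + lambda * sum |theta_{i+1} - theta_i|
// solved by ADMM.  The linear system of the theta-update, (W + rho D'D),
// is tridiagonal and solved in O(n) by the Thomas algorithm; the split
// variable d is exactly sparse (soft threshold), so its zero pattern gives
// the fused segmentation directly.
// [[Rcpp::export]]
List admm_weighted_fused_lasso(NumericVector z, NumericVector w, double lambda,
                               int max_iter, double tol,
                               Nullable<NumericVector> d0 = R_NilValue,
                               Nullable<NumericVector> u0 = R_NilValue) {
  int n = z.size();
  NumericVector theta(clone(z));
  if (n == 1) {
    return List::create(_["theta"] = theta,
                        _["d"] = NumericVector(0),
                        _["u"] = NumericVector(0));
  }
  int m = n - 1;
  NumericVector d(m), u(m), dth(m);
  if (d0.isNotNull()) d = clone(NumericVector(d0));
  if (u0.isNotNull()) u = clone(NumericVector(u0));
  bool warm = d0.isNotNull();
  double wbar = 0.0;
  for (int i = 0; i < n; ++i) wbar += w[i];
  wbar /= n;
  double rho = std::max(wbar, 1e-3);

  std::vector<double> diag(n), cprime(n), rhs(n), dprime(n);
  if (!warm) {
    for (int j = 0; j < m; ++j) d[j] = theta[j + 1] - theta[j];
  }

  for (int it = 0; it < max_iter; ++it) {
    // rhs = w*z + rho * D'(d - u)
    for (int i = 0; i < n; ++i) {
      double t = w[i] * z[i];
      if (i > 0)     t += rho * (d[i - 1] - u[i - 1]);
      if (i < n - 1) t -= rho * (d[i] - u[i]);
      rhs[i] = t;
    }
    // tridiagonal solve: diag_i = w_i + rho*deg_i, off-diagonals -rho
    for (int i = 0; i < n; ++i) {
      double deg = (i > 0 ? 1.0 : 0.0) + (i < n - 1 ? 1.0 : 0.0);
      diag[i] = w[i] + rho * deg;
    }
    cprime[0] = -rho / diag[0];
    dprime[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i) {
      double denom = diag[i] + rho * cprime[i - 1];
      cprime[i] = -rho / denom;
      dprime[i] = (rhs[i] + rho * dprime[i - 1]) / denom;
    }
    theta[n - 1] = dprime[n - 1];
    for (int i = n - 2; i >= 0; --i) {
      theta[i] = dprime[i] - cprime[i] * theta[i + 1];
    }
    // d-update (soft threshold) and dual update
    double r_prim = 0.0, r_dual = 0.0;
    double thr = lambda / rho;
    for (int j = 0; j < m; ++j) {
      dth[j] = theta[j + 1] - theta[j];
      double v = dth[j] + u[j];
      double dn = std::max(std::fabs(v) - thr, 0.0);
      dn = (v > 0 ? dn : -dn);
      r_dual = std::max(r_dual, rho * std::fabs(dn - d[j]));
      d[j] = dn;
      u[j] += dth[j] - d[j];
      r_prim = std::max(r_prim, std::fabs(dth[j] - d[j]));
    }
    if (r_prim < tol && r_dual < tol) break;
    // residual balancing keeps the iteration fast across lambda scales
    if ((it + 1) % 25 == 0) {
      if (r_prim > 10.0 * r_dual) {
        rho *= 2.0;
        for (int j = 0; j < m; ++j) u[j] /= 2.0;
      } else if (r_dual > 10.0 * r_prim) {
        rho /= 2.0;
        for (int j = 0; j < m; ++j) u[j] *= 2.0;
      }
    }
  }
  return List::create(_["theta"] = theta, _["d"] = d, _["u"] = u);
}
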