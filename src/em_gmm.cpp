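#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// EM iterations for a 1-D Gaussian mixture. Initial parameters come from R
// (seeded k-means); this loop only refines them. Component variances are
// floored at vfloor to prevent collapse onto single points; convergence is
// an absolute tolerance on the total log-likelihood.
// [[Rcpp::export(name = ".em_gmm")]]
List em_gmm(NumericVector x, NumericVector w0, NumericVector mu0,
            NumericVector v0, double vfloor, double tol, int max_iter) {
  const int n = x.size(), K = w0.size();
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> resp(static_cast<size_t>(n) * K);
  std::vector<double> ld(K);
  double ll = R_NegInf, ll_old = R_NegInf;
  bool floored = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    // E step with log-sum-exp
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        const double d = x[i] - mu[k];
        ld[k] = std::log(w[k]) - 0.5 * std::log(2.0 * M_PI * v[k]) -
                d * d / (2.0 * v[k]);
        if (ld[k] > mx) mx = ld[k];
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += std::exp(ld[k] - mx);
      const double lse = mx + std::log(s);
      ll += lse;
      for (int k = 0; k < K; ++k)
        resp[static_cast<size_t>(k) * n + i] = std::exp(ld[k] - lse);
    }
    // M step
    for (int k = 0; k < K; ++k) {
      const double *rk = &resp[static_cast<size_t>(k) * n];
      double nk = 0.0, sx = 0.0;
      for (int i = 0; i < n; ++i) { nk += rk[i]; sx += rk[i] * x[i]; }
      if (nk < 1e-10) nk = 1e-10;
      w[k] = nk / n;
      mu[k] = sx / nk;
      double sv = 0.0;
      for (int i = 0; i < n; ++i) {
        const double d = x[i] - mu[k];
        sv += rk[i] * d * d;
      }
      v[k] = sv / nk;
      if (v[k] < vfloor) { v[k] = vfloor; floored = true; }
    }
    if (R_finite(ll_old) && std::fabs(ll - ll_old) < tol) break;
    ll_old = ll;
  }

  return List::create(_["weights"] = NumericVector(w.begin(), w.end()),
                      _["means"] = NumericVector(mu.begin(), mu.end()),
                      _["variances"] = NumericVector(v.begin(), v.end()),
                      _["loglik"] = ll, _["floored"] = floored,
                      _["iterations"] = std::min(iter, max_iter));
}
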