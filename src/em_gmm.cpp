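#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// EM for a univariate Gaussian mixture. Responsibilities are computed in
// log space with a per-observation max shift; variances are floored to keep
// components from collapsing onto single points.
// [[Rcpp::export(name = ".em_gmm1_cpp")]]
List em_gmm1_cpp(NumericVector x, NumericVector mu0, NumericVector sd0,
                 NumericVector w0, double tol, int max_iter,
                 double var_floor) {
  const int n = x.size();
  const int k = mu0.size();
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sd(k), w(k);
  double wsum = 0.0;
  for (int j = 0; j < k; ++j) wsum += w0[j];
  for (int j = 0; j < k; ++j) {
    sd[j] = std::max(sd0[j], std::sqrt(var_floor));
    w[j] = w0[j] / wsum;
  }
  const double log2pi_half = 0.5 * std::log(2.0 * M_PI);
  std::vector<double> logd(n * k), resp(n * k);
  std::vector<double> trace;
  trace.reserve(max_iter);
  double ll = -INFINITY, ll_old = -INFINITY;

  for (int iter = 0; iter < max_iter; ++iter) {
    // E step (log densities + normalization)
    for (int j = 0; j < k; ++j) {
      const double lw = std::log(w[j]) - std::log(sd[j]) - log2pi_half;
      const double inv2v = 0.5 / (sd[j] * sd[j]);
      for (int i = 0; i < n; ++i) {
        const double d = x[i] - mu[j];
        logd[j * n + i] = lw - d * d * inv2v;
      }
    }
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double m = logd[i];
      for (int j = 1; j < k; ++j) m = std::max(m, logd[j * n + i]);
      double s = 0.0;
      for (int j = 0; j < k; ++j) {
        const double e = std::exp(logd[j * n + i] - m);
        resp[j * n + i] = e;
        s += e;
      }
      ll += m + std::log(s);
      const double inv_s = 1.0 / s;
      for (int j = 0; j < k; ++j) resp[j * n + i] *= inv_s;
    }
    trace.push_back(ll);
    if (iter > 0 && ll - ll_old < tol) break;
    ll_old = ll;
    // M step
    for (int j = 0; j < k; ++j) {
      double nk = 0.0, sx = 0.0;
      for (int i = 0; i < n; ++i) {
        nk += resp[j * n + i];
        sx += resp[j * n + i] * x[i];
      }
      const double mj = sx / nk;
      double sv = 0.0;
      for (int i = 0; i < n; ++i) {
        const double d = x[i] - mj;
        sv += resp[j * n + i] * d * d;
      }
      mu[j] = mj;
      sd[j] = std::sqrt(std::max(sv / nk, var_floor));
      w[j] = nk / n;
    }
  }
  return List::create(_["mu"] = NumericVector(mu.begin(), mu.end()),
                      _["sd"] = NumericVector(sd.begin(), sd.end()),
                      _["w"] = NumericVector(w.begin(), w.end()),
                      _["loglik"] = ll,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}
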