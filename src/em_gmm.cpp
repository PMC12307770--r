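#include <Rcpp.h>
using namespace Rcpp;

// EM for a K-component univariate Gaussian mixture.
// Returns the fitted parameters plus the per-iteration log-likelihood trace
// (EM guarantees it is non-decreasing up to the variance floor).
// [[Rcpp::export(name = ".em_gmm_1d_cpp")]]
List em_gmm_1d_cpp(NumericVector x, NumericVector mu0, double var0,
                   double tol, int max_iter, double var_floor,
                   bool equal_var) {
  const int n = x.size();
  const int K = mu0.size();
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> w(K, 1.0 / K), v(K, var0);
  std::vector<double> lp(K), r(K), nk(K), sum_rx(K), sum_rd2(K);
  NumericVector trace(max_iter);
  const double log2pi = std::log(2.0 * M_PI);
  double ll_old = R_NegInf;
  bool converged = false;
  int iter = 0;

  while (true) {
    ++iter;
    double ll = 0.0;
    std::fill(nk.begin(), nk.end(), 0.0);
    std::fill(sum_rx.begin(), sum_rx.end(), 0.0);
    std::fill(sum_rd2.begin(), sum_rd2.end(), 0.0);
    std::vector<double> cst(K), half_inv_v(K);
    for (int k = 0; k < K; ++k) {
      cst[k] = std::log(w[k]) - 0.5 * (log2pi + std::log(v[k]));
      half_inv_v[k] = 0.5 / v[k];
    }
    std::vector<double> sum_rx2(K, 0.0);
    for (int i = 0; i < n; ++i) {
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        const double d = x[i] - mu[k];
        lp[k] = cst[k] - d * d * half_inv_v[k];
        if (lp[k] > mx) mx = lp[k];
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += std::exp(lp[k] - mx);
      const double lse = mx + std::log(s);
      ll += lse;
      for (int k = 0; k < K; ++k) {
        r[k] = std::exp(lp[k] - lse);
        nk[k] += r[k];
        sum_rx[k] += r[k] * x[i];
        sum_rx2[k] += r[k] * x[i] * x[i];
      }
    }
    trace[iter - 1] = ll;
    // M-step; responsibility-weighted squared deviation around the new mean
    // expands to sum(r x^2) - 2 mu' sum(r x) + mu'^2 nk
    std::vector<double> mu_new(K);
    for (int k = 0; k < K; ++k) {
      const double nk_safe = std::max(nk[k], 1e-12);
      mu_new[k] = sum_rx[k] / nk_safe;
      w[k] = nk_safe / n;
      sum_rd2[k] = sum_rx2[k] - 2.0 * mu_new[k] * sum_rx[k] +
                   mu_new[k] * mu_new[k] * nk_safe;
      if (sum_rd2[k] < 0.0) sum_rd2[k] = 0.0;
    }
    if (equal_var) {
      double pool = 0.0;
      for (int k = 0; k < K; ++k) pool += sum_rd2[k];
      pool = std::max(pool / n, var_floor);
      for (int k = 0; k < K; ++k) v[k] = pool;
    } else {
      for (int k = 0; k < K; ++k) {
        v[k] = std::max(sum_rd2[k] / std::max(nk[k], 1e-12), var_floor);
      }
    }
    mu = mu_new;
    if (R_finite(ll) && ll - ll_old < tol && iter > 1) {
      converged = true;
      break;
    }
    if (iter >= max_iter) break;
    ll_old = ll;
  }
  return List::create(
      _["weights"] = NumericVector(w.begin(), w.end()),
      _["means"] = NumericVector(mu.begin(), mu.end()),
      _["variances"] = NumericVector(v.begin(), v.end()),
      _["loglik"] = trace[iter - 1],
      _["converged"] = converged,
      _["n_iter"] = iter,
      _["loglik_trace"] = trace[Range(0, iter - 1)]);
}
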