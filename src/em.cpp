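#include <Rcpp.h>
using namespace Rcpp;

// Univariate Gaussian-mixture EM from a given start.
// Returns R_NilValue when a component degenerates (sd < 1e-4 or an
// emptied component); otherwise a list with the fitted parameters, the
// final log-likelihood, the responsibility matrix and a convergence
// flag. The log-likelihood is checked non-decreasing every iteration.
// [[Rcpp::export(name = ".emRunCpp")]]
SEXP emRunCpp(NumericVector x, NumericVector mu0, NumericVector sd0,
              NumericVector w0, double tol, int maxIter) {
  const int n = x.size();
  const int k = mu0.size();
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sd(sd0.begin(), sd0.end());
  std::vector<double> w(w0.begin(), w0.end());
  NumericMatrix resp(n, k);
  const double log2pi = std::log(2.0 * M_PI);
  double ll = R_NegInf;
  bool converged = false;

  std::vector<double> cst(k), inv(k);
  for (int iter = 0; iter < maxIter; ++iter) {
    // E step with stable log-sum-exp; component constants hoisted
    for (int j = 0; j < k; ++j) {
      cst[j] = -std::log(sd[j]) - 0.5 * log2pi + std::log(w[j]);
      inv[j] = 1.0 / sd[j];
    }
    double llNew = 0.0;
    for (int j = 0; j < k; ++j) {
      double *col = &resp(0, j);
      const double c = cst[j], v = inv[j], m = mu[j];
      for (int i = 0; i < n; ++i) {
        double z = (x[i] - m) * v;
        col[i] = c - 0.5 * z * z;
      }
    }
    for (int i = 0; i < n; ++i) {
      double best = resp(i, 0);
      for (int j = 1; j < k; ++j) if (resp(i, j) > best) best = resp(i, j);
      double s = 0.0;
      for (int j = 0; j < k; ++j) {
        double e = std::exp(resp(i, j) - best);
        resp(i, j) = e;
        s += e;
      }
      llNew += best + std::log(s);
      double invS = 1.0 / s;
      for (int j = 0; j < k; ++j) resp(i, j) *= invS;
    }
    if (llNew < ll - 1e-8)
      stop("EM log-likelihood decreased; numerical defect");
    bool done = std::isfinite(ll) && (llNew - ll) < tol;
    ll = llNew;

    // M step
    for (int j = 0; j < k; ++j) {
      double nk = 0.0, sx = 0.0;
      for (int i = 0; i < n; ++i) { nk += resp(i, j); sx += resp(i, j) * x[i]; }
      if (nk < 1e-8) return R_NilValue;       // emptied component
      double m = sx / nk, sv = 0.0;
      for (int i = 0; i < n; ++i) {
        double dxi = x[i] - m;
        sv += resp(i, j) * dxi * dxi;
      }
      mu[j] = m;
      sd[j] = std::sqrt(sv / nk);
      w[j] = nk / n;
      if (sd[j] < 1e-4) return R_NilValue;    // degenerate spike
    }
    if (done) { converged = true; break; }
  }
  return List::create(_["mu"] = NumericVector(mu.begin(), mu.end()),
                      _["sd"] = NumericVector(sd.begin(), sd.end()),
                      _["w"] = NumericVector(w.begin(), w.end()),
                      _["logLik"] = ll,
                      _["resp"] = resp,
                      _["converged"] = converged);
}
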