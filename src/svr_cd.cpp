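#include <Rcpp.h>
using namespace Rcpp;

// Exact coordinate descent on the linear eps-SVR dual with regularised bias:
//   min_beta  0.5 * beta' K beta - y' beta + epsilon * ||beta||_1
//   s.t.      |beta_i| <= C
// where K = Xs Xs' + 1 (the +1 absorbs the intercept).  Each coordinate has
// a closed-form soft-threshold update; f = K beta is maintained
// incrementally.
// [[Rcpp::export]]
NumericVector svr_dual_cd(const NumericMatrix& K, const NumericVector& y,
                          double C, double epsilon, int max_iter,
                          double tol, NumericVector beta_init) {
  const int n = K.nrow();
  NumericVector beta = clone(beta_init);
  std::vector<double> f(n, 0.0);
  for (int i = 0; i < n; ++i)
    if (beta[i] != 0.0)
      for (int j = 0; j < n; ++j) f[j] += beta[i] * K(j, i);
  for (int it = 0; it < max_iter; ++it) {
    double delta_max = 0.0, bmax = 0.0;
    for (int i = 0; i < n; ++i) {
      const double kii = K(i, i);
      const double g = f[i] - kii * beta[i];
      const double r = y[i] - g;
      double b_new = 0.0;
      const double a = std::fabs(r) - epsilon;
      if (a > 0.0) b_new = (r > 0.0 ? a : -a) / kii;
      if (b_new > C) b_new = C;
      else if (b_new < -C) b_new = -C;
      const double d = b_new - beta[i];
      if (d != 0.0) {
        beta[i] = b_new;
        for (int j = 0; j < n; ++j) f[j] += d * K(j, i);
        if (std::fabs(d) > delta_max) delta_max = std::fabs(d);
      }
      if (std::fabs(beta[i]) > bmax) bmax = std::fabs(beta[i]);
    }
    if (delta_max < tol * (1.0 + bmax)) break;
  }
  return beta;
}
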