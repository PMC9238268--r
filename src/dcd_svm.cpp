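#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for a box-constrained SVM dual:
//   max_alpha  sum(alpha) - 0.5 * alpha' Q alpha,   lo <= alpha <= hi
// with Q[i][j] = y_i y_j K(x_i, x_j). The shifted boxes arise from the
// concave-convex (CCCP) majorization of the ramp loss, where flagged
// outliers get lo = -C, hi = 0. Maintains q = Q alpha for O(n) updates.
// [[Rcpp::export]]
NumericVector svm_dcd(NumericMatrix Q, NumericVector lo, NumericVector hi,
                      NumericVector alpha0, double tol = 1e-10,
                      int max_pass = 2000) {
  int n = Q.nrow();
  NumericVector alpha = clone(alpha0);
  std::vector<double> q(n, 0.0);
  for (int i = 0; i < n; ++i) {
    if (alpha[i] != 0.0) {
      for (int j = 0; j < n; ++j) q[j] += Q(j, i) * alpha[i];
    }
  }
  for (int pass = 0; pass < max_pass; ++pass) {
    double max_delta = 0.0;
    for (int i = 0; i < n; ++i) {
      double qii = Q(i, i);
      if (qii <= 0.0) continue;
      double cand = alpha[i] + (1.0 - q[i]) / qii;
      if (cand < lo[i]) cand = lo[i];
      if (cand > hi[i]) cand = hi[i];
      double delta = cand - alpha[i];
      if (delta != 0.0) {
        alpha[i] = cand;
        for (int j = 0; j < n; ++j) q[j] += Q(j, i) * delta;
        double ad = std::fabs(delta);
        if (ad > max_delta) max_delta = ad;
      }
    }
    if (max_delta < tol) break;
  }
  return alpha;
}
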