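#include <Rcpp.h>
using namespace Rcpp;

// Fused Adam update, applied in place to one parameter tensor and its
// first/second moment accumulators. The caller owns the only reference to
// these buffers (deep-copied when snapshotting best weights), so in-place
// mutation is safe and avoids eight full-size temporaries per step.
// [[Rcpp::export]]
void adam_update_(NumericVector p, NumericVector g, NumericVector m,
                  NumericVector v, double lr, int t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-7;
  const double c1 = 1.0 - std::pow(b1, t);
  const double c2 = 1.0 - std::pow(b2, t);
  const R_xlen_t n = p.size();
  if (g.size() != n || m.size() != n || v.size() != n)
    stop("adam_update_: length mismatch");
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = g[i];
    const double mi = b1 * m[i] + (1.0 - b1) * gi;
    const double vi = b2 * v[i] + (1.0 - b2) * gi * gi;
    m[i] = mi;
    v[i] = vi;
    p[i] -= lr * (mi / c1) / (std::sqrt(vi / c2) + eps);
  }
}
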