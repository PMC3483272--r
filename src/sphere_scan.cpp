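#include <Rcpp.h>
using namespace Rcpp;

// Weight-characterized closed balls around every subject, in one pass over the
// precomputed distance-sorted neighbor lists.
//
// For each center the walk accumulates subject weights in neighbor order until
// the running sum reaches the requested sphere weight W, then extends over the
// whole tie shell at the final radius (closed ball, so membership does not
// depend on subject input order). Inside-sphere diseased/healthy weights are
// accumulated alongside.
//
// Accumulators are long double: R's sum()/cumsum() accumulate in LDOUBLE, and
// the reference R path (sphere_at/sphere_table) must agree bitwise with this
// scan. The running cohort weight is rounded to double at every step exactly
// as cumsum() stores its intermediates.
//
// [[Rcpp::export]]
List cpp_sphere_scan(IntegerMatrix ord, NumericMatrix dmat,
                     NumericVector w, LogicalVector diseased, double W) {
  const int n = w.size();
  if (ord.nrow() != n || dmat.nrow() != n)
    stop("neighbor index does not match cohort size");
  NumericVector a_in(n), c_in(n), radius(n), cw(n);
  IntegerVector count(n);

  for (int i = 0; i < n; ++i) {
    long double acc = 0.0L, aI = 0.0L, cI = 0.0L;
    double r = 0.0;
    int j = 0;
    bool reached = false;
    for (; j < n; ++j) {
      const int idx = ord(i, j) - 1;
      acc += w[idx];
      if (diseased[idx]) aI += w[idx]; else cI += w[idx];
      if ((double) acc >= W) { reached = true; r = dmat(i, idx); break; }
    }
    if (!reached)
      stop("sphere weight exceeds total cohort weight");
    int m = j + 1;
    for (int j2 = j + 1; j2 < n; ++j2) {     // closed ball: keep the tie shell
      const int idx2 = ord(i, j2) - 1;
      if (dmat(i, idx2) != r) break;
      acc += w[idx2];
      if (diseased[idx2]) aI += w[idx2]; else cI += w[idx2];
      ++m;
    }
    a_in[i] = (double) aI;
    c_in[i] = (double) cI;
    radius[i] = r;
    cw[i] = (double) acc;
    count[i] = m;
  }
  return List::create(_["a_in"] = a_in, _["c_in"] = c_in,
                      _["count"] = count, _["radius"] = radius,
                      _["cohort_weight"] = cw);
}
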