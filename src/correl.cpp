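#include <Rcpp.h>
using namespace Rcpp;

// Pooled-origin survival correlators over a boolean state matrix
// (entities x frames).  Origins are 0-based frame indices; every origin must
// satisfy origin + max_lag < n_frames (checked by the R caller).
// Numerator/denominator follow the ratio-of-pooled-sums normalization: the
// denominator is the total number of (entity, origin) pairs active at t = 0.

// Continuous survival: entity counted at lag l iff active at the origin and
// at every stored frame in between (zero-tolerance for gaps).
// [[Rcpp::export]]
List corr_continuous_cpp(LogicalMatrix states, IntegerVector origins,
                         int max_lag) {
  int ne = states.nrow();
  NumericVector num(max_lag + 1);
  double den = 0.0;
  for (int oi = 0; oi < origins.size(); ++oi) {
    int o = origins[oi];
    for (int e = 0; e < ne; ++e) {
      if (!states(e, o)) continue;
      den += 1.0;
      int l = 0;
      while (l <= max_lag && states(e, o + l)) {
        num[l] += 1.0;
        ++l;
      }
    }
  }
  return List::create(_["num"] = num, _["den"] = den);
}

// Intermittent (presence-at-endpoints) correlator: entity counted at lag l
// iff active at the origin and at the lag frame, regardless of gaps.
// [[Rcpp::export]]
List corr_intermittent_cpp(LogicalMatrix states, IntegerVector origins,
                           int max_lag) {
  int ne = states.nrow();
  NumericVector num(max_lag + 1);
  double den = 0.0;
  for (int oi = 0; oi < origins.size(); ++oi) {
    int o = origins[oi];
    for (int e = 0; e < ne; ++e) {
      if (!states(e, o)) continue;
      den += 1.0;
      for (int l = 0; l <= max_lag; ++l)
        if (states(e, o + l)) num[l] += 1.0;
    }
  }
  return List::create(_["num"] = num, _["den"] = den);
}
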