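#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Batched weighted Kolmogorov-Smirnov running-sum enrichment scores.
//
// absw: |metric|^weight of the universe in ranked order (descending metric).
// pos: k x n_sets matrix of 1-based positions of each set's genes in that
// ranked order. The running sum increases at a hit by the hit's share of the
// set's total weight and decreases by 1/(N-k) at each miss; between hits it
// is linear in the number of misses, so the extreme deviation is attained
// immediately before or after a hit (or at the endpoints, where it is 0).
// [[Rcpp::export]]
NumericVector es_batch_cpp(NumericVector absw, IntegerMatrix pos) {
  const int N = absw.size();
  const int k = pos.nrow();
  const int n_sets = pos.ncol();
  if (k >= N) stop("Gene set must be a proper subset of the universe.");
  const double miss_step = 1.0 / (double)(N - k);
  NumericVector out(n_sets);
  std::vector<int> p(k);
  for (int s = 0; s < n_sets; ++s) {
    for (int i = 0; i < k; ++i) {
      int v = pos(i, s);
      if (v < 1 || v > N) stop("Rank position out of range.");
      p[i] = v;
    }
    std::sort(p.begin(), p.end());
    double sumw = 0.0;
    for (int i = 0; i < k; ++i) sumw += absw[p[i] - 1];
    const bool uniform = !(sumw > 0.0);  // all-zero weights: unweighted steps
    double running = 0.0, best = 0.0;
    for (int i = 0; i < k; ++i) {
      const double miss_before = (double)(p[i] - 1 - i) * miss_step;
      const double before = running - miss_before;
      if (std::fabs(before) > std::fabs(best)) best = before;
      running += uniform ? 1.0 / (double)k : absw[p[i] - 1] / sumw;
      const double after = running - miss_before;
      if (std::fabs(after) > std::fabs(best)) best = after;
    }
    out[s] = best;
  }
  return out;
}
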