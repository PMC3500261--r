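#include <Rcpp.h>
#include <vector>
#include <utility>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Maximal two-arc statistic for circular binary segmentation.
// Scans all arc pairs (i, j], 0 <= i < j <= m, requiring both the arc and
// its complement to hold at least minw points. The statistic is the
// difference of arc/complement means scaled by the region's own sd, which
// is permutation-invariant, so the sd is computed once.
static void best_split(const std::vector<double>& x, int minw,
                       int& bi, int& bj, double& bt) {
  const int m = (int)x.size();
  bt = -1.0; bi = -1; bj = -1;
  if (m < 2 * minw) return;
  std::vector<double> S(m + 1, 0.0);
  for (int k = 0; k < m; ++k) S[k + 1] = S[k] + x[k];
  const double total = S[m];
  const double mean = total / m;
  double ss = 0.0;
  for (int k = 0; k < m; ++k) { double d = x[k] - mean; ss += d * d; }
  const double sd = std::sqrt(ss / (m - 1));
  if (sd <= 0.0) return;
  for (int i = 0; i <= m - minw; ++i) {
    const int jmax = std::min(m, i + m - minw);
    for (int j = i + minw; j <= jmax; ++j) {
      const int k = j - i;
      const double sum_in = S[j] - S[i];
      const double mi = sum_in / k;
      const double mo = (total - sum_in) / (m - k);
      const double t = std::fabs(mi - mo) /
                       (sd * std::sqrt(1.0 / k + 1.0 / (m - k)));
      if (t > bt) { bt = t; bi = i; bj = j; }
    }
  }
}

// Permutation p-value for the observed max statistic, with early stopping:
// once the exceedance count guarantees p > alpha the scan aborts.
static double perm_p(const std::vector<double>& x, int minw, double tobs,
                     int nperm, double alpha) {
  std::vector<double> y = x;
  const int m = (int)y.size();
  const int stop_at = (int)std::ceil(alpha * nperm);
  int nge = 0;
  for (int p = 0; p < nperm; ++p) {
    for (int k = m - 1; k > 0; --k) {
      int idx = (int)(unif_rand() * (k + 1));
      if (idx > k) idx = k;
      std::swap(y[k], y[idx]);
    }
    int bi, bj; double bt;
    best_split(y, minw, bi, bj, bt);
    if (bt >= tobs) {
      ++nge;
      if (nge > stop_at) return (double)nge / (double)(p + 1);
    }
  }
  return (double)nge / (double)nperm;
}

// [[Rcpp::export(name = ".cbs_changepoints")]]
IntegerVector cbs_changepoints(NumericVector x, double alpha, int nperm,
                               int minw, int min_region) {
  const int n = x.size();
  std::vector<std::pair<int, int> > stack;  // [lo, hi), 0-based
  std::vector<int> ends;
  stack.push_back(std::make_pair(0, n));
  while (!stack.empty()) {
    const int lo = stack.back().first;
    const int hi = stack.back().second;
    stack.pop_back();
    const int m = hi - lo;
    bool split = false;
    if (m >= min_region && m >= 2 * minw) {
      std::vector<double> seg(x.begin() + lo, x.begin() + hi);
      int bi, bj; double bt;
      best_split(seg, minw, bi, bj, bt);
      if (bt > 0.0) {
        const double p = perm_p(seg, minw, bt, nperm, alpha);
        if (p < alpha) {
          if (bi > 0) stack.push_back(std::make_pair(lo, lo + bi));
          stack.push_back(std::make_pair(lo + bi, lo + bj));
          if (lo + bj < hi) stack.push_back(std::make_pair(lo + bj, hi));
          split = true;
        }
      }
    }
    if (!split) ends.push_back(hi);
  }
  std::sort(ends.begin(), ends.end());
  return wrap(ends);  // 1-based inclusive segment end indices
}
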