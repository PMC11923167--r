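#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Sliding percentile with R's type-7 quantile semantics (linear
// interpolation between order statistics) over a centered window of
// half-width `half` samples, truncated at the trace edges. The window is
// re-sorted incrementally: one value leaves and one enters per step, each an
// O(w) vector shuffle, giving O(n * w) worst case with a small constant --
// ample for session-length traces at the rates used here.
// [[Rcpp::export(name = ".sliding_percentile_cpp")]]
NumericVector sliding_percentile_cpp(NumericVector x, int half, double p) {
  const int n = x.size();
  NumericVector out(n);
  if (n == 0) return out;

  int lo = 0;                       // current window = [lo, hi], inclusive
  int hi = std::min(half, n - 1);
  std::vector<double> win(x.begin() + lo, x.begin() + hi + 1);
  std::sort(win.begin(), win.end());

  for (int i = 0; i < n; ++i) {
    int nlo = std::max(0, i - half);
    int nhi = std::min(n - 1, i + half);
    while (hi < nhi) {              // value enters on the right
      ++hi;
      double v = x[hi];
      win.insert(std::upper_bound(win.begin(), win.end(), v), v);
    }
    while (lo < nlo) {              // value leaves on the left
      double v = x[lo];
      win.erase(std::lower_bound(win.begin(), win.end(), v));
      ++lo;
    }
    const int m = static_cast<int>(win.size());
    const double h = (m - 1) * p;   // type-7 position
    const int k = static_cast<int>(std::floor(h));
    const double frac = h - k;
    double q = win[k];
    if (frac > 0.0 && k + 1 < m) q += frac * (win[k + 1] - win[k]);
    out[i] = q;
  }
  return out;
}
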