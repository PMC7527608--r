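#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Running median with an even default order of 10, matching the despiking
// filter contract: interior windows span samples [i - (w/2 - 1), i + w/2]
// (so a non-decreasing run passes through with zero lag), ties on even
// windows break to the lower median, and windows shrink symmetrically at
// the series boundaries (odd length, true median) instead of padding.
// [[Rcpp::export]]
NumericVector running_median_lower(NumericVector x, int order = 10) {
  const int n = x.size();
  if (order < 2)
    stop("'order' must be at least 2");
  if (n <= order)
    stop("series length (%d) must exceed the filter order (%d)", n, order);
  NumericVector out(n);
  std::vector<double> w;
  w.reserve(order + 1);
  int back, fwd; // interior window extents
  if (order % 2 == 0) {
    back = order / 2 - 1;
    fwd = order / 2;
  } else {
    back = (order - 1) / 2;
    fwd = back;
  }
  for (int i = 0; i < n; ++i) {
    int lo, hi;
    if (i - back >= 0 && i + fwd <= n - 1) {
      lo = i - back;
      hi = i + fwd;
    } else {
      int s = std::min(i, n - 1 - i);
      lo = i - s;
      hi = i + s;
    }
    const int len = hi - lo + 1;
    w.assign(x.begin() + lo, x.begin() + hi + 1);
    // lower median: element at 0-based rank floor((len - 1) / 2)
    const int k = (len - 1) / 2;
    std::nth_element(w.begin(), w.begin() + k, w.end());
    out[i] = w[k];
  }
  return out;
}

// Centered moving average; the window shrinks symmetrically at the edges.
// [[Rcpp::export]]
NumericVector moving_average_centered(NumericVector x, int window = 5) {
  const int n = x.size();
  if (window < 2)
    stop("'window' must be at least 2");
  if (n <= window)
    stop("series length (%d) must exceed the window (%d)", n, window);
  NumericVector out(n);
  const int half = window / 2; // window 5 -> [i-2, i+2]
  for (int i = 0; i < n; ++i) {
    int s = std::min(half, std::min(i, n - 1 - i));
    double acc = 0.0;
    for (int j = i - s; j <= i + s; ++j) acc += x[j];
    out[i] = acc / (2 * s + 1);
  }
  return out;
}

// Host read-time recursion for the simulator's polling loop: frame j
// (captured at capture[j] ms) is logged at
//   h[j] = max(capture[j], h[j-1] + period[j])
// where period[j] is the loop iteration time, pre-drawn in R from the
// warm-up distribution while the host clock is still inside the warm-up
// span and from the steady-state distribution afterwards.
// [[Rcpp::export]]
NumericVector host_read_times(NumericVector capture, NumericVector warm_period,
                              NumericVector stable_period, double warmup_end_ms) {
  const int n = capture.size();
  if (warm_period.size() < n || stable_period.size() < n)
    stop("period vectors must be at least as long as 'capture'");
  NumericVector h(n);
  double prev = 0.0;
  for (int j = 0; j < n; ++j) {
    const double p = (prev < warmup_end_ms) ? warm_period[j] : stable_period[j];
    const double ready = prev + p;
    h[j] = (capture[j] > ready) ? capture[j] : ready;
    prev = h[j];
  }
  return h;
}
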