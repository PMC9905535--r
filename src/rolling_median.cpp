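#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Trailing moving median over a fixed sample-count window.
//
// Maintains the current window as a sorted buffer; each step removes the
// departing value and inserts the arriving one at its ordered position
// (binary search + memmove), so the cost is O(n * w) element moves -- far
// cheaper in practice than per-window sorting for the window sizes used in
// routine monitoring (hundreds of samples) and fast enough for the
// Monte-Carlo run-length simulations.
//
// Entries before the first full window are NA. Even windows return the
// midpoint of the two central order statistics.

// [[Rcpp::export]]
NumericVector roll_median_trailing(NumericVector x, int w) {
  const int n = x.size();
  if (w < 1)
    stop("window must be a positive integer");
  if (w > n)
    stop("window (%d) exceeds series length (%d)", w, n);
  for (int i = 0; i < n; ++i)
    if (NumericVector::is_na(x[i]))
      stop("moving median input must not contain missing values (index %d)",
           i + 1);

  NumericVector out(n, NA_REAL);
  std::vector<double> buf(x.begin(), x.begin() + w);
  std::sort(buf.begin(), buf.end());

  const int lo = (w - 1) / 2, hi = w / 2;  // equal for odd w
  out[w - 1] = (buf[lo] + buf[hi]) / 2.0;

  for (int i = w; i < n; ++i) {
    const double dep = x[i - w], arr = x[i];
    buf.erase(std::lower_bound(buf.begin(), buf.end(), dep));
    buf.insert(std::upper_bound(buf.begin(), buf.end(), arr), arr);
    out[i] = (buf[lo] + buf[hi]) / 2.0;
  }
  return out;
}
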