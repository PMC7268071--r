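#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// direct-form-I IIR filter, zero initial conditions
static void iir_filter(const std::vector<double> &x, std::vector<double> &y,
                       const std::vector<double> &b,
                       const std::vector<double> &a) {
  const int n = x.size(), nb = b.size(), na = a.size();
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < nb && j <= i; ++j) acc += b[j] * x[i - j];
    for (int j = 1; j < na && j <= i; ++j) acc -= a[j] * y[i - j];
    y[i] = acc / a[0];
  }
}

// Zero-phase (forward-backward) IIR filtering of each column, with odd
// reflection padding at both ends to suppress startup transients.
// [[Rcpp::export]]
NumericMatrix filtfilt_cols_cpp(NumericMatrix X, NumericVector bcoef,
                                NumericVector acoef) {
  const int n = X.nrow(), m = X.ncol();
  const std::vector<double> b(bcoef.begin(), bcoef.end());
  const std::vector<double> a(acoef.begin(), acoef.end());
  const int order = std::max(b.size(), a.size()) - 1;
  const int pad = std::min(n - 1, std::max(10 * order, 24));
  const int np = n + 2 * pad;
  NumericMatrix out(n, m);
  std::vector<double> xe(np), y1(np), y2(np);
  for (int c = 0; c < m; ++c) {
    // odd extension: 2*x[0] - x[pad..1] | x | 2*x[n-1] - x[n-2..]
    for (int i = 0; i < pad; ++i) xe[i] = 2.0 * X(0, c) - X(pad - i, c);
    for (int i = 0; i < n; ++i) xe[pad + i] = X(i, c);
    for (int i = 0; i < pad; ++i)
      xe[pad + n + i] = 2.0 * X(n - 1, c) - X(n - 2 - i, c);
    iir_filter(xe, y1, b, a);
    std::reverse(y1.begin(), y1.end());
    iir_filter(y1, y2, b, a);
    std::reverse(y2.begin(), y2.end());
    for (int i = 0; i < n; ++i) out(i, c) = y2[pad + i];
  }
  return out;
}
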