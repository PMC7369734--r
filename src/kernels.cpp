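#include <Rcpp.h>
using namespace Rcpp;

// Orbit of the random-iteration algorithm: map indices are drawn in R (so
// the RNG stream is R's), only the affine iteration runs here.
// [[Rcpp::export]]
NumericMatrix chaos_game_orbit(NumericVector a, NumericVector b,
                               NumericVector c, NumericVector d,
                               NumericVector e, NumericVector f,
                               IntegerVector pick, double x0, double y0) {
  const int n = pick.size();
  NumericMatrix out(n, 2);
  double x = x0, y = y0;
  for (int k = 0; k < n; ++k) {
    const int i = pick[k] - 1;
    const double xn = a[i] * x + b[i] * y + e[i];
    const double yn = c[i] * x + d[i] * y + f[i];
    x = xn;
    y = yn;
    out(k, 0) = x;
    out(k, 1) = y;
  }
  return out;
}

// All N(N-1)/2 unordered pair distances, binned on the fly: O(N^2) time,
// O(n_bins) memory. Distances land in bin floor(r / width); r exactly at
// the top edge goes to the last bin.
// [[Rcpp::export]]
NumericVector pair_distance_counts(NumericVector x, NumericVector y,
                                   double width, int n_bins) {
  const int n = x.size();
  NumericVector counts(n_bins);
  for (int i = 0; i < n - 1; ++i) {
    const double xi = x[i], yi = y[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[j] - xi, dy = y[j] - yi;
      const double r = std::sqrt(dx * dx + dy * dy);
      int b = static_cast<int>(r / width);
      if (b >= n_bins) b = n_bins - 1;
      counts[b] += 1.0;
    }
  }
  return counts;
}
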