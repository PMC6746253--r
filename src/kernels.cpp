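#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Median of each row of a numeric matrix (used for the per-pixel median
// projection across membrane-kernel rotations).
// [[Rcpp::export]]
NumericVector cpp_row_medians(NumericMatrix x) {
  const int n = x.nrow(), k = x.ncol();
  NumericVector out(n);
  std::vector<double> buf(k);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < k; ++j) buf[j] = x(i, j);
    const int m = k / 2;
    std::nth_element(buf.begin(), buf.begin() + m, buf.end());
    double med = buf[m];
    if (k % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + m - 1, buf.begin() + m);
      med = 0.5 * (med + buf[m - 1]);
    }
    out[i] = med;
  }
  return out;
}

// Square-window median filter with nearest-pixel (replicate) edge handling.
// radius 0 is the identity.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix x, int radius) {
  const int h = x.nrow(), w = x.ncol();
  if (radius <= 0) return clone(x);
  NumericMatrix out(h, w);
  const int win = 2 * radius + 1;
  std::vector<double> buf(win * win);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      int n = 0;
      for (int dj = -radius; dj <= radius; ++dj) {
        const int jj = clampi(j + dj, 0, w - 1);
        for (int di = -radius; di <= radius; ++di) {
          buf[n++] = x(clampi(i + di, 0, h - 1), jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.begin() + n);
      out(i, j) = buf[n / 2];  // n is odd
    }
  }
  return out;
}

// Bilateral filter: Gaussian spatial weight (sd sigma_spatial, window radius
// given) times Gaussian range weight on intensity difference (sd sigma_range).
// Replicate edge handling.
// [[Rcpp::export]]
NumericMatrix cpp_bilateral(NumericMatrix x, int radius, double sigma_spatial,
                            double sigma_range) {
  const int h = x.nrow(), w = x.ncol();
  NumericMatrix out(h, w);
  const int win = 2 * radius + 1;
  std::vector<double> sw(win * win);
  for (int dj = -radius; dj <= radius; ++dj)
    for (int di = -radius; di <= radius; ++di)
      sw[(dj + radius) * win + (di + radius)] =
          std::exp(-0.5 * (di * di + dj * dj) / (sigma_spatial * sigma_spatial));
  const double inv2sr2 = 0.5 / (sigma_range * sigma_range);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      const double c = x(i, j);
      double acc = 0.0, wacc = 0.0;
      for (int dj = -radius; dj <= radius; ++dj) {
        const int jj = clampi(j + dj, 0, w - 1);
        for (int di = -radius; di <= radius; ++di) {
          const double v = x(clampi(i + di, 0, h - 1), jj);
          const double d = v - c;
          const double wt = sw[(dj + radius) * win + (di + radius)] *
                            std::exp(-d * d * inv2sr2);
          acc += wt * v;
          wacc += wt;
        }
      }
      out(i, j) = acc / wacc;
    }
  }
  return out;
}
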