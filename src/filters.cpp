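#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Reflective (symmetric, edge-inclusive) index: ... c b a | a b c ... | c b a
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Grayscale erosion (erode = true) or dilation with a structuring element
// given as offsets (di = row, dj = col) and heights h.  Non-flat SEs are
// supported (rolling-ball cap).  Edges use reflective padding.
// erosion:  (f (-) b)(x) = min_y f(x + y) - b(y)
// dilation: (f (+) b)(x) = max_y f(x - y) + b(y)
// [[Rcpp::export]]
NumericMatrix cpp_gray_morph(NumericMatrix img, IntegerVector di,
                             IntegerVector dj, NumericVector h, bool erode) {
  const int nr = img.nrow(), nc = img.ncol(), K = di.size();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(),
            erode ? R_PosInf : R_NegInf);
  const double *src = img.begin();
  double *dst = out.begin();
  for (int k = 0; k < K; ++k) {
    const int oi = erode ? di[k] : -di[k];
    const int oj = erode ? dj[k] : -dj[k];
    const double hk = h[k];
    for (int j = 0; j < nc; ++j) {
      const int sj = reflect_idx(j + oj, nc);
      const double *col = src + (size_t)sj * nr;
      double *ocol = dst + (size_t)j * nr;
      // interior rows can skip reflection
      int i = 0;
      if (erode) {
        for (; i < nr; ++i) {
          const int si = (i + oi >= 0 && i + oi < nr) ? i + oi
                                                      : reflect_idx(i + oi, nr);
          const double v = col[si] - hk;
          if (v < ocol[i]) ocol[i] = v;
        }
      } else {
        for (; i < nr; ++i) {
          const int si = (i + oi >= 0 && i + oi < nr) ? i + oi
                                                      : reflect_idx(i + oi, nr);
          const double v = col[si] + hk;
          if (v > ocol[i]) ocol[i] = v;
        }
      }
    }
  }
  return out;
}

// Neighbourhood median at (i, j); reflective padding at the borders, a
// precomputed linear-offset fast path in the interior.
static inline double nbhd_median(const double *src, int nr, int nc, int i,
                                 int j, const int *di, const int *dj,
                                 const int *lin, int K, bool interior,
                                 std::vector<double> &buf) {
  if (interior) {
    const double *p = src + (size_t)j * nr + i;
    for (int k = 0; k < K; ++k) buf[k] = p[lin[k]];
  } else {
    for (int k = 0; k < K; ++k) {
      const int si = reflect_idx(i + di[k], nr);
      const int sj = reflect_idx(j + dj[k], nc);
      buf[k] = src[(size_t)sj * nr + si];
    }
  }
  const int m = K / 2;
  std::nth_element(buf.begin(), buf.begin() + m, buf.begin() + K);
  double med = buf[m];
  if (K % 2 == 0) {
    double lo = *std::max_element(buf.begin(), buf.begin() + m);
    med = 0.5 * (med + lo);
  }
  return med;
}

// Rank (median) filter over an arbitrary neighbourhood given as offsets,
// reflective padding.  Median of an even-sized set is the mean of the two
// central order statistics.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix img, IntegerVector di,
                                IntegerVector dj) {
  const int nr = img.nrow(), nc = img.ncol(), K = di.size();
  NumericMatrix out(nr, nc);
  std::vector<double> buf(K);
  std::vector<int> lin(K);
  int rad = 0;
  for (int k = 0; k < K; ++k) {
    lin[k] = di[k] + dj[k] * nr;
    rad = std::max(rad, std::max(std::abs(di[k]), std::abs(dj[k])));
  }
  const double *src = img.begin();
  for (int j = 0; j < nc; ++j) {
    const bool jin = (j >= rad && j < nc - rad);
    for (int i = 0; i < nr; ++i) {
      const bool interior = jin && i >= rad && i < nr - rad;
      out(i, j) = nbhd_median(src, nr, nc, i, j, di.begin(), dj.begin(),
                              lin.data(), K, interior, buf);
    }
  }
  return out;
}

// Replace pixels deviating from the local median (neighbourhood given as
// offsets, centre included) by more than `threshold` with that median.
// [[Rcpp::export]]
NumericMatrix cpp_remove_outliers(NumericMatrix img, IntegerVector di,
                                  IntegerVector dj, double threshold) {
  const int nr = img.nrow(), nc = img.ncol(), K = di.size();
  NumericMatrix out(nr, nc);
  std::vector<double> buf(K);
  std::vector<int> lin(K);
  int rad = 0;
  for (int k = 0; k < K; ++k) {
    lin[k] = di[k] + dj[k] * nr;
    rad = std::max(rad, std::max(std::abs(di[k]), std::abs(dj[k])));
  }
  const double *src = img.begin();
  for (int j = 0; j < nc; ++j) {
    const bool jin = (j >= rad && j < nc - rad);
    for (int i = 0; i < nr; ++i) {
      const bool interior = jin && i >= rad && i < nr - rad;
      const double med = nbhd_median(src, nr, nc, i, j, di.begin(),
                                     dj.begin(), lin.data(), K, interior,
                                     buf);
      const double v = img(i, j);
      out(i, j) = (std::abs(v - med) > threshold) ? med : v;
    }
  }
  return out;
}

// Add a set of truncated Gaussian spots to an image in place-like fashion
// (returns a new matrix).  x = column coordinate, y = row coordinate, both
// continuous with pixel centres at integer - 0.5.  Truncation at trunc_sigma.
// [[Rcpp::export]]
NumericMatrix cpp_render_spots(NumericMatrix img, NumericVector y,
                               NumericVector x, NumericVector amp,
                               double sigma, double trunc_sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out = clone(img);
  const double rad = trunc_sigma * sigma;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double r2max = rad * rad;
  for (int k = 0; k < y.size(); ++k) {
    const double yc = y[k], xc = x[k], a = amp[k];
    const int i0 = std::max(0, (int)std::floor(yc - rad));
    const int i1 = std::min(nr - 1, (int)std::ceil(yc + rad));
    const int j0 = std::max(0, (int)std::floor(xc - rad));
    const int j1 = std::min(nc - 1, (int)std::ceil(xc + rad));
    for (int j = j0; j <= j1; ++j) {
      const double dx = (j + 0.5) - xc;
      for (int i = i0; i <= i1; ++i) {
        const double dy = (i + 0.5) - yc;
        const double r2 = dx * dx + dy * dy;
        if (r2 <= r2max) out(i, j) += a * std::exp(-r2 * inv2s2);
      }
    }
  }
  return out;
}
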