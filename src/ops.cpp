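#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// 1D squared distance transform (Felzenszwalb & Huttenlocher lower envelope).
static void dt1d(const std::vector<double>& f, std::vector<double>& d) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Large finite stand-in for "no seed in this line": INFINITY would give
// NaN in the envelope intersections. Squared distances compare correctly
// as long as image diagonals stay far below 1e10 pixels.
static const double EDT_FAR = 1e20;

// Squared Euclidean distance to the nearest TRUE pixel. All-false input
// yields EDT_FAR-scale values everywhere.
// [[Rcpp::export(name = ".edt_sq")]]
NumericMatrix edt_sq(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> f, d;
  // columns first
  f.assign(nr, 0.0); d.assign(nr, 0.0);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = mask(i, j) ? 0.0 : EDT_FAR;
    dt1d(f, d);
    for (int i = 0; i < nr; ++i) out(i, j) = d[i];
  }
  // then rows
  f.assign(nc, 0.0); d.assign(nc, 0.0);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = out(i, j);
    dt1d(f, d);
    for (int j = 0; j < nc; ++j) out(i, j) = d[j];
  }
  return out;
}

// Connected-component labelling, BFS; connectivity 4 or 8. Labels start at 1
// in scan order; background stays 0.
// [[Rcpp::export(name = ".label_cc")]]
IntegerMatrix label_cc(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dx4[] = {-1, 1, 0, 0}, dy4[] = {0, 0, -1, 1};
  const int dx8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dy8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dx = connectivity == 8 ? dx8 : dx4;
  const int* dy = connectivity == 8 ? dy8 : dy4;
  const int nd = connectivity == 8 ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int d = 0; d < nd; ++d) {
          int ii = p.first + dx[d], jj = p.second + dy[d];
          if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
          if (mask(ii, jj) && !lab(ii, jj)) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}

// Separable convolution with one odd-length kernel applied along rows then
// columns; replicate padding at the borders.
// [[Rcpp::export(name = ".conv_sep")]]
NumericMatrix conv_sep(NumericMatrix img, NumericVector kernel) {
  const int nr = img.nrow(), nc = img.ncol(), nk = kernel.size();
  const int h = nk / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j) {       // vertical pass
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int k = 0; k < nk; ++k) {
        int ii = i + k - h;
        if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
        acc += img(ii, j) * kernel[k];
      }
      tmp(i, j) = acc;
    }
  }
  for (int j = 0; j < nc; ++j) {       // horizontal pass
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int k = 0; k < nk; ++k) {
        int jj = j + k - h;
        if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
        acc += tmp(i, jj) * kernel[k];
      }
      out(i, j) = acc;
    }
  }
  return out;
}
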