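// Low-level image primitives shared by the registration, morphology and
// trace-extraction code. Coordinate convention (package-wide): 0-based
// (row, col), pixel centers at integer coordinates.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Bilinear sample at (r, c); returns `outside` when the point falls outside
// the pixel-center grid. Exact at integer coordinates.
static inline double sample_bilinear(const NumericMatrix& img, double r, double c,
                                     double outside, bool* valid) {
  const int H = img.nrow(), W = img.ncol();
  if (r < 0.0 || c < 0.0 || r > H - 1.0 || c > W - 1.0) {
    if (valid) *valid = false;
    return outside;
  }
  if (valid) *valid = true;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  if (r0 == H - 1) r0 = H - 2 < 0 ? 0 : H - 2;
  if (c0 == W - 1) c0 = W - 2 < 0 ? 0 : W - 2;
  const double fr = r - r0, fc = c - c0;
  if (H == 1 && W == 1) return img(0, 0);
  if (H == 1) return (1.0 - fc) * img(0, c0) + fc * img(0, c0 + 1);
  if (W == 1) return (1.0 - fr) * img(r0, 0) + fr * img(r0 + 1, 0);
  return (1.0 - fr) * ((1.0 - fc) * img(r0, c0) + fc * img(r0, c0 + 1)) +
         fr * ((1.0 - fc) * img(r0 + 1, c0) + fc * img(r0 + 1, c0 + 1));
}

// Map fixed-grid pixel (r, c) through the affine transform: q = A (p - cen) + cen + off.
static inline void affine_map(double r, double c, const double* lin, const double* off,
                              const double* cen, double* qr, double* qc) {
  const double dr = r - cen[0], dc = c - cen[1];
  *qr = lin[0] * dr + lin[1] * dc + cen[0] + off[0];
  *qc = lin[2] * dr + lin[3] * dc + cen[1] + off[1];
}

// [[Rcpp::export]]
NumericMatrix cpp_warp_affine(const NumericMatrix& img, const NumericVector& lin,
                              const NumericVector& off, const NumericVector& cen) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  const double* L = lin.begin();
  const double* O = off.begin();
  const double* C = cen.begin();
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double qr, qc;
      affine_map((double)i, (double)j, L, O, C, &qr, &qc);
      out(i, j) = sample_bilinear(img, qr, qc, 0.0, nullptr);
    }
  return out;
}

// Mean-squares metric between `fixed` and `moving` warped by the affine
// transform, over the overlap domain only. `stride` subsamples the fixed
// grid (used to accelerate the optimizer's inner loop).
// [[Rcpp::export]]
List cpp_ms_affine(const NumericMatrix& fixed, const NumericMatrix& moving,
                   const NumericVector& lin, const NumericVector& off,
                   const NumericVector& cen, const int stride = 1) {
  const int H = fixed.nrow(), W = fixed.ncol();
  const double* L = lin.begin();
  const double* O = off.begin();
  const double* C = cen.begin();
  double acc = 0.0;
  long n = 0;
  for (int j = 0; j < W; j += stride)
    for (int i = 0; i < H; i += stride) {
      double qr, qc;
      bool valid;
      affine_map((double)i, (double)j, L, O, C, &qr, &qc);
      const double v = sample_bilinear(moving, qr, qc, 0.0, &valid);
      if (valid) {
        const double d = fixed(i, j) - v;
        acc += d * d;
        ++n;
      }
    }
  return List::create(_["ms"] = n > 0 ? acc / n : NA_REAL, _["n"] = (double)n);
}

// Sample `img` at arbitrary coordinate maps (same shape as the output grid).
// [[Rcpp::export]]
NumericMatrix cpp_warp_map(const NumericMatrix& img, const NumericMatrix& map_r,
                           const NumericMatrix& map_c) {
  const int H = map_r.nrow(), W = map_r.ncol();
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = sample_bilinear(img, map_r(i, j), map_c(i, j), 0.0, nullptr);
  return out;
}

// [[Rcpp::export]]
List cpp_ms_map(const NumericMatrix& fixed, const NumericMatrix& moving,
                const NumericMatrix& map_r, const NumericMatrix& map_c) {
  const int H = fixed.nrow(), W = fixed.ncol();
  double acc = 0.0;
  long n = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      bool valid;
      const double v = sample_bilinear(moving, map_r(i, j), map_c(i, j), 0.0, &valid);
      if (valid) {
        const double d = fixed(i, j) - v;
        acc += d * d;
        ++n;
      }
    }
  return List::create(_["ms"] = n > 0 ? acc / n : NA_REAL, _["n"] = (double)n);
}

// Separable Gaussian blur, reflected boundary, kernel truncated at 3 sigma.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(const NumericMatrix& img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0.0) return clone(img);
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  double ksum = 0.0;
  for (int t = -rad; t <= rad; ++t) {
    k[t + rad] = std::exp(-0.5 * (double)t * t / (sigma * sigma));
    ksum += k[t + rad];
  }
  for (double& v : k) v /= ksum;
  NumericMatrix tmp(H, W), out(H, W);
  // rows (vertical pass)
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int t = -rad; t <= rad; ++t) {
        int ii = i + t;
        if (ii < 0) ii = -ii - 1;
        if (ii >= H) ii = 2 * H - ii - 1;
        if (ii < 0) ii = 0;
        if (ii >= H) ii = H - 1;
        acc += k[t + rad] * img(ii, j);
      }
      tmp(i, j) = acc;
    }
  // cols (horizontal pass)
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int t = -rad; t <= rad; ++t) {
        int jj = j + t;
        if (jj < 0) jj = -jj - 1;
        if (jj >= W) jj = 2 * W - jj - 1;
        if (jj < 0) jj = 0;
        if (jj >= W) jj = W - 1;
        acc += k[t + rad] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  return out;
}

// 8-connected component labeling of a logical mask (two-pass union-find).
// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0); // parent[0] unused
  auto find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 1;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      if (!mask(i, j)) { lab(i, j) = 0; continue; }
      int best = 0;
      const int di[4] = {-1, -1, -1, 0};
      const int dj[4] = {-1, 0, 1, -1};
      int nb[4], nn = 0;
      for (int t = 0; t < 4; ++t) {
        const int ii = i + di[t], jj = j + dj[t];
        if (ii >= 0 && ii < H && jj >= 0 && jj < W && lab(ii, jj) > 0)
          nb[nn++] = lab(ii, jj);
      }
      if (nn == 0) {
        parent.push_back(next);
        lab(i, j) = next++;
      } else {
        best = nb[0];
        for (int t = 1; t < nn; ++t) best = std::min(best, nb[t]);
        lab(i, j) = best;
        for (int t = 0; t < nn; ++t) unite(best, nb[t]);
      }
    }
  // second pass: flatten and renumber compactly
  std::vector<int> newid(next, 0);
  int nlab = 0;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j)
      if (lab(i, j) > 0) {
        const int r = find(lab(i, j));
        if (newid[r] == 0) newid[r] = ++nlab;
        lab(i, j) = newid[r];
      }
  return lab;
}

// 1-D squared-distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (in px) from every pixel to the nearest TRUE pixel.
// All-false mask returns +Inf everywhere.
// [[Rcpp::export]]
NumericMatrix cpp_edt(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  NumericMatrix d2(H, W);
  const double INF = 1e18;
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) f[i] = mask(i, j) ? 0.0 : INF;
    dt1d(f, d, H);
    for (int i = 0; i < H; ++i) d2(i, j) = d[i];
  }
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) f[j] = d2(i, j);
    dt1d(f, d, W);
    for (int j = 0; j < W; ++j) d2(i, j) = d[j];
  }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      d2(i, j) = d2(i, j) >= INF ? R_PosInf : std::sqrt(d2(i, j));
  return d2;
}

// Per-frame ROI means for a movie stored as an (H*W) x T matrix.
// `idx` holds 0-based linear indices into each frame column.
// [[Rcpp::export]]
NumericVector cpp_roi_means(const NumericMatrix& flat, const IntegerVector& idx) {
  const int T = flat.ncol();
  const int n = idx.size();
  NumericVector out(T);
  for (int t = 0; t < T; ++t) {
    double acc = 0.0;
    for (int k = 0; k < n; ++k) acc += flat(idx[k], t);
    out[t] = acc / n;
  }
  return out;
}
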