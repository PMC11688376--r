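#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Feature maps are R arrays dim (H, W, C) in column-major order (H fastest).
// im2col output is transposed relative to the textbook layout: a
// (Ho*Wo) x (k*k*C) matrix whose row index is the output pixel (ho fastest)
// and whose column index is r = ki + k*kj + k*k*c. With weights stored as a
// (k*k*C) x Cout matrix, the convolution is a single GEMM col %*% W whose
// result is already in (Ho, Wo, Cout) column-major order, and all memory
// access here is contiguous for stride 1.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int k,
                         int stride, int pad, int dil) {
  const int span = dil * (k - 1) + 1;
  const int Ho = (H + 2 * pad - span) / stride + 1;
  const int Wo = (W + 2 * pad - span) / stride + 1;
  const std::size_t npix = (std::size_t)Ho * Wo;
  NumericMatrix out(npix, k * k * C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (std::size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double* col = op + npix * (std::size_t)(ki + k * kj + k * k * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + dil * kj;
          double* dst = col + (std::size_t)wo * Ho;
          if (wi < 0 || wi >= W) {
            std::memset(dst, 0, sizeof(double) * Ho);
            continue;
          }
          const double* src = xc + (std::size_t)wi * H;
          const int off = dil * ki - pad;  // hi = ho*stride + off
          if (stride == 1) {
            // valid ho range: 0 <= ho + off < H
            int lo = std::max(0, -off);
            int hi = std::min(Ho, H - off);
            if (lo > 0) std::memset(dst, 0, sizeof(double) * lo);
            if (hi < Ho) std::memset(dst + std::max(hi, 0), 0,
                                     sizeof(double) * (Ho - std::max(hi, 0)));
            if (hi > lo) std::memcpy(dst + lo, src + lo + off,
                                     sizeof(double) * (hi - lo));
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              const int hh = ho * stride + off;
              dst[ho] = (hh >= 0 && hh < H) ? src[hh] : 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add the (Ho*Wo) x (k*k*C) gradient columns back into (H, W, C).
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int k,
                         int stride, int pad, int dil) {
  const int span = dil * (k - 1) + 1;
  const int Ho = (H + 2 * pad - span) / stride + 1;
  const int Wo = (W + 2 * pad - span) / stride + 1;
  const std::size_t npix = (std::size_t)Ho * Wo;
  NumericVector out((std::size_t)H * W * C);
  double* op = out.begin();
  const double* cp = cols.begin();
  for (int c = 0; c < C; ++c) {
    double* xc = op + (std::size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double* col = cp + npix * (std::size_t)(ki + k * kj + k * k * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + dil * kj;
          if (wi < 0 || wi >= W) continue;
          double* dstc = xc + (std::size_t)wi * H;
          const double* src = col + (std::size_t)wo * Ho;
          const int off = dil * ki - pad;
          if (stride == 1) {
            int lo = std::max(0, -off);
            int hi = std::min(Ho, H - off);
            for (int ho = lo; ho < hi; ++ho) dstc[ho + off] += src[ho];
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              const int hh = ho * stride + off;
              if (hh >= 0 && hh < H) dstc[hh] += src[ho];
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}

// 8-connected component labeling of a binary matrix (union-find, two pass).
// Returns an integer matrix of labels (0 = background, components 1..n).
// [[Rcpp::export]]
IntegerMatrix label8_cpp(IntegerMatrix m) {
  const int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  auto find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (m(i, j) == 0) continue;
      int best = 0;
      // previously scanned 8-neighbors: (i-1,j), (i,j-1), (i-1,j-1), (i+1,j-1)
      const int di[4] = {-1, 0, -1, 1};
      const int dj[4] = {0, -1, -1, -1};
      for (int t = 0; t < 4; ++t) {
        int ni = i + di[t], nj = j + dj[t];
        if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
        int l = lab(ni, nj);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(best, l);
        }
      }
      if (best == 0) { best = ++next; parent.push_back(best); }
      lab(i, j) = best;
    }
  }
  // second pass: flatten labels and renumber consecutively
  std::vector<int> remap(next + 1, 0);
  int nlab = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int r = find(l);
      if (remap[r] == 0) remap[r] = ++nlab;
      lab(i, j) = remap[r];
    }
  return lab;
}
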