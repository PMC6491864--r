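#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Feature maps are R arrays with dim (D, H, W, C, B), column-major.
// im2col unrolls k^3 neighbourhoods (dilated, zero-padded) into a
// (C*k^3) x (Do*Ho*Wo*B) matrix so convolution becomes one GEMM.

static inline int out_extent(int n, int k, int stride, int dil, int pad) {
  return (n + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// [[Rcpp::export(name = ".im2col3d")]]
NumericMatrix im2col3d(NumericVector x, IntegerVector dims,
                       int k, int stride, int dil, int pad) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3], B = dims[4];
  const int Do = out_extent(D, k, stride, dil, pad);
  const int Ho = out_extent(H, k, stride, dil, pad);
  const int Wo = out_extent(W, k, stride, dil, pad);
  if (Do < 1 || Ho < 1 || Wo < 1)
    stop("input too small for kernel/stride/dilation");
  const int K = C * k * k * k;
  const R_xlen_t ncol = (R_xlen_t)Do * Ho * Wo * B;
  NumericMatrix out(K, ncol);
  const double* xp = x.begin();
  double* op = out.begin();
  const R_xlen_t sH = D, sW = (R_xlen_t)D * H, sC = (R_xlen_t)D * H * W,
                 sB = (R_xlen_t)D * H * W * C;
  for (int b = 0; b < B; ++b) {
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        for (int d = 0; d < Do; ++d) {
          R_xlen_t col = d + (R_xlen_t)Do * (h + (R_xlen_t)Ho * (w + (R_xlen_t)Wo * b));
          double* dst = op + col * K;
          for (int kw = 0; kw < k; ++kw) {
            int iw = w * stride - pad + dil * kw;
            for (int kh = 0; kh < k; ++kh) {
              int ih = h * stride - pad + dil * kh;
              for (int kd = 0; kd < k; ++kd) {
                int id = d * stride - pad + dil * kd;
                R_xlen_t row0 = (R_xlen_t)(kd + k * (kh + k * kw)) * C;
                if (id < 0 || id >= D || ih < 0 || ih >= H || iw < 0 || iw >= W) {
                  for (int c = 0; c < C; ++c) dst[c + row0] = 0.0;
                } else {
                  R_xlen_t src = id + sH * ih + sW * iw + sB * b;
                  for (int c = 0; c < C; ++c) dst[c + row0] = xp[src + sC * c];
                }
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3d: scatter-add columns back onto the padded grid.
// [[Rcpp::export(name = ".col2im3d")]]
NumericVector col2im3d(NumericMatrix cols, IntegerVector dims,
                       int k, int stride, int dil, int pad) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3], B = dims[4];
  const int Do = out_extent(D, k, stride, dil, pad);
  const int Ho = out_extent(H, k, stride, dil, pad);
  const int Wo = out_extent(W, k, stride, dil, pad);
  const int K = C * k * k * k;
  if (cols.nrow() != K || cols.ncol() != (R_xlen_t)Do * Ho * Wo * B)
    stop("cols dimensions inconsistent with target grid");
  NumericVector x((R_xlen_t)D * H * W * C * B);
  x.attr("dim") = dims;
  double* xp = x.begin();
  const double* cp = cols.begin();
  const R_xlen_t sH = D, sW = (R_xlen_t)D * H, sC = (R_xlen_t)D * H * W,
                 sB = (R_xlen_t)D * H * W * C;
  for (int b = 0; b < B; ++b) {
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        for (int d = 0; d < Do; ++d) {
          R_xlen_t col = d + (R_xlen_t)Do * (h + (R_xlen_t)Ho * (w + (R_xlen_t)Wo * b));
          const double* src = cp + col * K;
          for (int kw = 0; kw < k; ++kw) {
            int iw = w * stride - pad + dil * kw;
            if (iw < 0 || iw >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int ih = h * stride - pad + dil * kh;
              if (ih < 0 || ih >= H) continue;
              for (int kd = 0; kd < k; ++kd) {
                int id = d * stride - pad + dil * kd;
                if (id < 0 || id >= D) continue;
                R_xlen_t dstv = id + sH * ih + sW * iw + sB * b;
                R_xlen_t row0 = (R_xlen_t)(kd + k * (kh + k * kw)) * C;
                for (int c = 0; c < C; ++c) xp[dstv + sC * c] += src[c + row0];
              }
            }
          }
        }
      }
    }
  }
  return x;
}

// 2x2x2 max pooling, stride 2. Returns pooled values and the 1-based
// linear index of each winner for the backward scatter.
// [[Rcpp::export(name = ".maxpool3d_fwd")]]
List maxpool3d_fwd(NumericVector x, IntegerVector dims) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3], B = dims[4];
  if (D % 2 || H % 2 || W % 2) stop("spatial dims must be even for 2x2x2 pooling");
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Do * Ho * Wo * C * B);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, C, B);
  const double* xp = x.begin();
  const R_xlen_t sH = D, sW = (R_xlen_t)D * H, sC = (R_xlen_t)D * H * W;
  R_xlen_t o = 0;
  for (int cb = 0; cb < C * B; ++cb) {
    R_xlen_t base_cb = (R_xlen_t)cb * sC * 1; // contiguous over (c,b)
    base_cb = (R_xlen_t)cb * D * H * W;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        for (int d = 0; d < Do; ++d) {
          double best = R_NegInf; R_xlen_t besti = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh)
              for (int dd = 0; dd < 2; ++dd) {
                R_xlen_t i = base_cb + (2 * d + dd) + sH * (2 * h + dh) + sW * (2 * w + dw);
                if (xp[i] > best) { best = xp[i]; besti = i; }
              }
          y[o] = best;
          idx[o] = (int)(besti + 1);
          ++o;
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool3d_bwd")]]
NumericVector maxpool3d_bwd(NumericVector gy, IntegerVector idx, IntegerVector dims_in) {
  NumericVector gx((R_xlen_t)dims_in[0] * dims_in[1] * dims_in[2] * dims_in[3] * dims_in[4]);
  gx.attr("dim") = dims_in;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i] - 1] += gy[i];
  return gx;
}

// Connected components of a 3D binary mask (6 or 26 connectivity),
// breadth-first flood fill. Returns integer label array, labels ordered
// by first (smallest) linear voxel index of each component.
// [[Rcpp::export(name = ".label_components3d")]]
IntegerVector label_components3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int D = dims[0], H = dims[1], W = dims[2];
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");
  IntegerVector lab((R_xlen_t)D * H * W);
  lab.attr("dim") = dims;
  std::vector<std::array<int,3>> offs;
  for (int dw = -1; dw <= 1; ++dw)
    for (int dh = -1; dh <= 1; ++dh)
      for (int dd = -1; dd <= 1; ++dd) {
        if (!dd && !dh && !dw) continue;
        int manh = std::abs(dd) + std::abs(dh) + std::abs(dw);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dd, dh, dw});
      }
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < lab.size(); ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++next;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int d = (int)(v % D), h = (int)((v / D) % H), w = (int)(v / ((R_xlen_t)D * H));
      for (const auto& o : offs) {
        int nd = d + o[0], nh = h + o[1], nw = w + o[2];
        if (nd < 0 || nd >= D || nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
        R_xlen_t u = nd + (R_xlen_t)D * (nh + (R_xlen_t)H * nw);
        if (mask[u] && !lab[u]) { lab[u] = next; q.push(u); }
      }
    }
  }
  return lab;
}

// For each boundary voxel in A (rows: 0-based ijk), the minimum Euclidean
// distance (physical units) to any boundary voxel in B.
// [[Rcpp::export(name = ".min_surface_dists")]]
NumericVector min_surface_dists(IntegerMatrix A, IntegerMatrix B, NumericVector spacing) {
  const int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    double ax = A(i,0) * sx, ay = A(i,1) * sy, az = A(i,2) * sz;
    for (int j = 0; j < m; ++j) {
      double dx = ax - B(j,0) * sx, dy = ay - B(j,1) * sy, dz = az - B(j,2) * sz;
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
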