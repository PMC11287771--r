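// Dense and depth-wise 2-D convolution, and 2x2 max pooling, with exact
// analytic gradients. These are the only compute-heavy primitives of the
// network; everything else lives in R.
//
// Array layout convention (matches R column-major arrays):
//   feature stacks  x : dim (H, W, C, N)   element (h,w,c,n) at h + H*(w + W*(c + C*n))
//   dense weights   w : dim (kh, kw, Cin, Cout)
//   depthwise       w : dim (k, k, C)
// Stride is always 1; padding/dilation are caller-chosen (size-preserving in
// this package). The dense convolution is im2col + single-precision GEMM
// (the network trains in float32, as is conventional). The col matrix is
// pixel-major (HW x K), so both the im2col fill and the GEMM output scatter
// reduce to contiguous column-run copies.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>
using namespace Rcpp;

typedef arma::fmat fmat;

// reusable buffer pool for the large im2col workspaces: training allocates
// a few hundred MB of identical-shaped buffers every iteration, so buffers
// are recycled instead of returned to the allocator
static std::vector<fmat*> g_pool;
static fmat* pool_get(arma::uword r, arma::uword c) {
  for (std::size_t i = 0; i < g_pool.size(); ++i)
    if (g_pool[i]->n_rows == r && g_pool[i]->n_cols == c) {
      fmat* p = g_pool[i];
      g_pool.erase(g_pool.begin() + i);
      return p;
    }
  return new fmat(r, c);
}
static void pool_put(fmat* p) {
  if (!p) return;
  if (g_pool.size() < 16) g_pool.push_back(p); else delete p;
}
static void col_finalizer(fmat* p) { pool_put(p); }
typedef XPtr<fmat, PreserveStorage, col_finalizer> ColPtr;

// fill column k of the (ld x K) col block for one frame: a shifted copy of
// channel c with offset (dh, dw); rows outside the image are zero
static void im2col_fill(const double* x, int H, int W,
                        int dh, int dw, float* colk) {
  const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
  for (int w = 0; w < W; ++w) {
    float* dst = colk + (std::size_t)w * H;
    const int wc = w + dw;
    if (wc < 0 || wc >= W) { std::memset(dst, 0, H * sizeof(float)); continue; }
    const double* src = x + (std::size_t)wc * H + dh;
    for (int h = 0; h < h0; ++h) dst[h] = 0.0f;
    for (int h = h0; h < h1; ++h) dst[h] = (float)src[h];
    for (int h = h1; h < H; ++h) dst[h] = 0.0f;
  }
}

// inverse: add column k of the col block back into channel c with the same
// offset (gradient w.r.t. the input)
static void col2im_add(const float* colk, int H, int W,
                       int dh, int dw, double* dx) {
  const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
  for (int w = 0; w < W; ++w) {
    const float* src = colk + (std::size_t)w * H;
    const int wc = w + dw;
    if (wc < 0 || wc >= W) continue;
    double* dst = dx + (std::size_t)wc * H + dh;
    for (int h = h0; h < h1; ++h) dst[h] += (double)src[h];
  }
}

// weights (kh,kw,Cin,Cout) -> Wt (K x Cout), K ordered (c, ki, kj) kj fastest
static fmat weight_matrix_t(const double* w, int kh, int kw, int Cin, int Cout) {
  fmat Wt(kh * kw * Cin, Cout);
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int ki = 0; ki < kh; ++ki)
        for (int kj = 0; kj < kw; ++kj)
          Wt((c * kh + ki) * kw + kj, o) =
            (float)w[ki + kh * (kj + kw * (c + Cin * o))];
  return Wt;
}

static int chunk_frames(int K, int HW) {
  // cap the im2col buffer at ~64 MB
  double per = (double)K * HW * sizeof(float);
  int n = (int)std::floor(64e6 / per);
  return n < 1 ? 1 : n;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                             int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("input channels (%d) do not match weights (%d)", Cin, (int)wd[2]);
  const int HW = H * W, K = Cin * kh * kw;
  fmat Wt = weight_matrix_t(w.begin(), kh, kw, Cin, Cout);
  NumericVector y((std::size_t)HW * Cout * N);
  const int CH = chunk_frames(K, HW);
  const std::size_t ld = (std::size_t)HW * std::min(CH, N);
  fmat col(ld, K);
  for (int n0 = 0; n0 < N; n0 += CH) {
    const int nc = std::min(CH, N - n0);
    for (int i = 0; i < nc; ++i) {
      const double* xf = x.begin() + (std::size_t)(n0 + i) * HW * Cin;
      for (int c = 0; c < Cin; ++c)
        for (int ki = 0; ki < kh; ++ki)
          for (int kj = 0; kj < kw; ++kj)
            im2col_fill(xf + (std::size_t)c * HW, H, W,
                        ki * dil - pad, kj * dil - pad,
                        col.colptr((c * kh + ki) * kw + kj) + (std::size_t)i * HW);
    }
    fmat Yt = col.rows(0, (std::size_t)nc * HW - 1) * Wt;   // (nc*HW x Cout)
    for (int i = 0; i < nc; ++i)
      for (int o = 0; o < Cout; ++o) {
        double* yp = y.begin() + (std::size_t)HW * (o + (std::size_t)Cout * (n0 + i));
        const float* sp = Yt.colptr(o) + (std::size_t)i * HW;
        const double bo = b[o];
        for (int pix = 0; pix < HW; ++pix) yp[pix] = (double)sp[pix] + bo;
      }
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int pad, int dil, bool need_dx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int HW = H * W, K = Cin * kh * kw;
  fmat Wt = weight_matrix_t(w.begin(), kh, kw, Cin, Cout);
  fmat dWt(K, Cout, arma::fill::zeros);
  NumericVector db(Cout), dw(w.size()), dx(need_dx ? x.size() : 0);
  const int CH = chunk_frames(K, HW);
  const std::size_t ld = (std::size_t)HW * std::min(CH, N);
  fmat col(ld, K), dYt(ld, Cout);
  for (int n0 = 0; n0 < N; n0 += CH) {
    const int nc = std::min(CH, N - n0);
    for (int i = 0; i < nc; ++i) {
      const double* xf = x.begin() + (std::size_t)(n0 + i) * HW * Cin;
      for (int c = 0; c < Cin; ++c)
        for (int ki = 0; ki < kh; ++ki)
          for (int kj = 0; kj < kw; ++kj)
            im2col_fill(xf + (std::size_t)c * HW, H, W,
                        ki * dil - pad, kj * dil - pad,
                        col.colptr((c * kh + ki) * kw + kj) + (std::size_t)i * HW);
      for (int o = 0; o < Cout; ++o) {
        const double* dp = dy.begin() + (std::size_t)HW * (o + (std::size_t)Cout * (n0 + i));
        float* dst = dYt.colptr(o) + (std::size_t)i * HW;
        double s = 0.0;
        for (int pix = 0; pix < HW; ++pix) { dst[pix] = (float)dp[pix]; s += dp[pix]; }
        db[o] += s;
      }
    }
    const arma::uword last = (std::size_t)nc * HW - 1;
    dWt += col.rows(0, last).t() * dYt.rows(0, last);
    if (need_dx) {
      fmat colg = dYt.rows(0, last) * Wt.t();                // (nc*HW x K)
      for (int i = 0; i < nc; ++i) {
        double* dxf = dx.begin() + (std::size_t)(n0 + i) * HW * Cin;
        for (int c = 0; c < Cin; ++c)
          for (int ki = 0; ki < kh; ++ki)
            for (int kj = 0; kj < kw; ++kj)
              col2im_add(colg.colptr((c * kh + ki) * kw + kj) + (std::size_t)i * HW,
                         H, W, ki * dil - pad, kj * dil - pad,
                         dxf + (std::size_t)c * HW);
      }
    }
  }
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int ki = 0; ki < kh; ++ki)
        for (int kj = 0; kj < kw; ++kj)
          dw[ki + kh * (kj + kw * (c + Cin * o))] =
            (double)dWt((c * kh + ki) * kw + kj, o);
  dw.attr("dim") = wd;
  if (need_dx) dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// depth-wise convolution: each channel convolved with its own k x k kernel
// [[Rcpp::export(name = ".dwconv2d_fwd")]]
NumericVector dwconv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                               int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  if (wd[2] != C) stop("depthwise weights have %d channels, input has %d", (int)wd[2], C);
  const int HW = H * W;
  NumericVector y(x.size());
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (std::size_t)HW * (c + (std::size_t)C * n);
      double* yc = y.begin() + (std::size_t)HW * (c + (std::size_t)C * n);
      const double* wc = w.begin() + (std::size_t)kh * kw * c;
      const double bc = b[c];
      for (int pix = 0; pix < HW; ++pix) yc[pix] = bc;
      for (int ki = 0; ki < kh; ++ki)
        for (int kj = 0; kj < kw; ++kj) {
          const int dh = ki * dil - pad, dwv = kj * dil - pad;
          const double wv = wc[ki + kh * kj];
          if (wv == 0.0) continue;
          const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          for (int wq = 0; wq < W; ++wq) {
            const int wcq = wq + dwv;
            if (wcq < 0 || wcq >= W) continue;
            double* dst = yc + (std::size_t)wq * H;
            const double* src = xc + (std::size_t)wcq * H + dh;
            for (int h = h0; h < h1; ++h) dst[h] += wv * src[h];
          }
        }
    }
  y.attr("dim") = xd;
  return y;
}

// [[Rcpp::export(name = ".dwconv2d_bwd")]]
List dwconv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                      int pad, int dil, bool need_dx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  const int HW = H * W;
  NumericVector dw(w.size()), db(C), dx(need_dx ? x.size() : 0);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (std::size_t)HW * (c + (std::size_t)C * n);
      const double* dyc = dy.begin() + (std::size_t)HW * (c + (std::size_t)C * n);
      double* dxc = need_dx ? dx.begin() + (std::size_t)HW * (c + (std::size_t)C * n) : 0;
      const double* wc = w.begin() + (std::size_t)kh * kw * c;
      double* dwc = dw.begin() + (std::size_t)kh * kw * c;
      double s = 0.0;
      for (int pix = 0; pix < HW; ++pix) s += dyc[pix];
      db[c] += s;
      for (int ki = 0; ki < kh; ++ki)
        for (int kj = 0; kj < kw; ++kj) {
          const int dh = ki * dil - pad, dwv = kj * dil - pad;
          const double wv = wc[ki + kh * kj];
          const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          double acc = 0.0;
          for (int wq = 0; wq < W; ++wq) {
            const int wcq = wq + dwv;
            if (wcq < 0 || wcq >= W) continue;
            const double* g = dyc + (std::size_t)wq * H;
            const double* src = xc + (std::size_t)wcq * H + dh;
            for (int h = h0; h < h1; ++h) acc += g[h] * src[h];
            if (need_dx) {
              double* dst = dxc + (std::size_t)wcq * H + dh;
              for (int h = h0; h < h1; ++h) dst[h] += g[h] * wv;
            }
          }
          dwc[ki + kh * kj] += acc;
        }
    }
  dw.attr("dim") = wd;
  if (need_dx) dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2; ties broken toward the first element scanned
// (h-major within the window) so the backward scatter is deterministic.
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((std::size_t)Ho * Wo * C * N);
  IntegerVector idx(y.size());
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t base = (std::size_t)H * W * (c + (std::size_t)C * n);
      const std::size_t obase = (std::size_t)Ho * Wo * (c + (std::size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300; int bi = -1;
          for (int dw_ = 0; dw_ < 2; ++dw_)
            for (int dh = 0; dh < 2; ++dh) {
              const int h = 2 * ho + dh, w_ = 2 * wo + dw_;
              const std::size_t ii = base + h + (std::size_t)H * w_;
              if (x[ii] > best) { best = x[ii]; bi = (int)ii; }
            }
          y[obase + ho + (std::size_t)Ho * wo] = best;
          idx[obase + ho + (std::size_t)Ho * wo] = bi;
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd_cpp(IntegerVector idx, NumericVector dy, IntegerVector xdim) {
  std::size_t n = (std::size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  dx.attr("dim") = xdim;
  return dx;
}

// LeakyReLU forward/backward (elementwise; hot path, hence C++)
// [[Rcpp::export(name = ".lrelu_fwd")]]
NumericVector lrelu_fwd_cpp(NumericVector x, double a) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double v = x[i];
    y[i] = v >= 0 ? v : a * v;
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export(name = ".lrelu_bwd")]]
NumericVector lrelu_bwd_cpp(NumericVector x, NumericVector dy, double a) {
  NumericVector dx(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    dx[i] = x[i] >= 0 ? dy[i] : a * dy[i];
  dx.attr("dim") = x.attr("dim");
  return dx;
}

// training-mode convolution keeping the im2col matrix for the backward pass
// (a heap fmat handed to R as an external pointer); falls back to the
// recompute path for very large inputs
// [[Rcpp::export(name = ".conv2d_fwd_keep")]]
List conv2d_fwd_keep_cpp(NumericVector x, NumericVector w, NumericVector b,
                         int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("input channels (%d) do not match weights (%d)", Cin, (int)wd[2]);
  const int HW = H * W, K = Cin * kh * kw;
  const double bytes = (double)HW * N * K * sizeof(float);
  if (bytes > 1.2e9) {
    NumericVector y = conv2d_fwd_cpp(x, w, b, pad, dil);
    return List::create(_["y"] = y, _["col"] = R_NilValue);
  }
  fmat Wt = weight_matrix_t(w.begin(), kh, kw, Cin, Cout);
  ColPtr colp(pool_get((std::size_t)HW * N, K), true);
  fmat& col = *colp;
  for (int i = 0; i < N; ++i) {
    const double* xf = x.begin() + (std::size_t)i * HW * Cin;
    for (int c = 0; c < Cin; ++c)
      for (int ki = 0; ki < kh; ++ki)
        for (int kj = 0; kj < kw; ++kj)
          im2col_fill(xf + (std::size_t)c * HW, H, W,
                      ki * dil - pad, kj * dil - pad,
                      col.colptr((c * kh + ki) * kw + kj) + (std::size_t)i * HW);
  }
  fmat Yt = col * Wt;
  NumericVector y((std::size_t)HW * Cout * N);
  for (int i = 0; i < N; ++i)
    for (int o = 0; o < Cout; ++o) {
      double* yp = y.begin() + (std::size_t)HW * (o + (std::size_t)Cout * i);
      const float* sp = Yt.colptr(o) + (std::size_t)i * HW;
      const double bo = b[o];
      for (int pix = 0; pix < HW; ++pix) yp[pix] = (double)sp[pix] + bo;
    }
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return List::create(_["y"] = y, _["col"] = colp);
}

// backward pass reusing the cached im2col matrix
// [[Rcpp::export(name = ".conv2d_bwd_cached")]]
List conv2d_bwd_cached_cpp(SEXP colsexp, IntegerVector xdim, NumericVector w,
                           NumericVector dy, int pad, int dil, bool need_dx) {
  ColPtr colp(colsexp);
  fmat& col = *colp;
  IntegerVector wd = w.attr("dim");
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int HW = H * W, K = Cin * kh * kw;
  fmat Wt = weight_matrix_t(w.begin(), kh, kw, Cin, Cout);
  fmat dYt((std::size_t)HW * N, Cout);
  NumericVector db(Cout), dw(w.size()), dx(need_dx ? (R_xlen_t)HW * Cin * N : 0);
  for (int i = 0; i < N; ++i)
    for (int o = 0; o < Cout; ++o) {
      const double* dp = dy.begin() + (std::size_t)HW * (o + (std::size_t)Cout * i);
      float* dst = dYt.colptr(o) + (std::size_t)i * HW;
      double s = 0.0;
      for (int pix = 0; pix < HW; ++pix) { dst[pix] = (float)dp[pix]; s += dp[pix]; }
      db[o] += s;
    }
  fmat dWt = col.t() * dYt;
  if (need_dx) {
    fmat* colgp = pool_get((std::size_t)HW * N, K);
    *colgp = dYt * Wt.t();
    for (int i = 0; i < N; ++i) {
      double* dxf = dx.begin() + (std::size_t)i * HW * Cin;
      for (int c = 0; c < Cin; ++c)
        for (int ki = 0; ki < kh; ++ki)
          for (int kj = 0; kj < kw; ++kj)
            col2im_add(colgp->colptr((c * kh + ki) * kw + kj) + (std::size_t)i * HW,
                       H, W, ki * dil - pad, kj * dil - pad,
                       dxf + (std::size_t)c * HW);
    }
    pool_put(colgp);
  }
  // return the cached col buffer to the pool (release() invokes the
  // pool-returning finalizer); it is consumed exactly once
  colp.release();
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int ki = 0; ki < kh; ++ki)
        for (int kj = 0; kj < kw; ++kj)
          dw[ki + kh * (kj + kw * (c + Cin * o))] =
            (double)dWt((c * kh + ki) * kw + kj, o);
  dw.attr("dim") = wd;
  if (need_dx) dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
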