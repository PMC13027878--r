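// Dense 2D convolution / transposed convolution / max-pooling kernels.
// Tensor layout everywhere: column-major R arrays [H, W, C, N].
// Convolution weights: [KH, KW, Cin, Cout]; transposed-convolution
// weights: [KH, KW, Cout, Cin] (i.e. the weight of the underlying
// adjoint convolution).  im2col row index: kh + KH*(kw + KW*c).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;

static void im2col_one(const double* x, int H, int W, int C, int KH, int KW,
                       int stride, int pad, int Ho, int Wo, double* col) {
  const int K = KH * KW * C;
  for (int ox = 0; ox < Wo; ++ox) {
    for (int oy = 0; oy < Ho; ++oy) {
      double* cp = col + (size_t)(oy + (size_t)Ho * ox) * K;
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (size_t)c * H * W;
        for (int kw = 0; kw < KW; ++kw) {
          int ix = ox * stride - pad + kw;
          bool okx = (ix >= 0 && ix < W);
          for (int kh = 0; kh < KH; ++kh) {
            int iy = oy * stride - pad + kh;
            double v = 0.0;
            if (okx && iy >= 0 && iy < H) v = xc[iy + (size_t)ix * H];
            cp[kh + KH * (kw + KW * c)] = v;
          }
        }
      }
    }
  }
}

static void col2im_one(const double* col, int H, int W, int C, int KH, int KW,
                       int stride, int pad, int Ho, int Wo, double* x) {
  const int K = KH * KW * C;
  for (int ox = 0; ox < Wo; ++ox) {
    for (int oy = 0; oy < Ho; ++oy) {
      const double* cp = col + (size_t)(oy + (size_t)Ho * ox) * K;
      for (int c = 0; c < C; ++c) {
        double* xc = x + (size_t)c * H * W;
        for (int kw = 0; kw < KW; ++kw) {
          int ix = ox * stride - pad + kw;
          if (ix < 0 || ix >= W) continue;
          for (int kh = 0; kh < KH; ++kh) {
            int iy = oy * stride - pad + kh;
            if (iy < 0 || iy >= H) continue;
            xc[iy + (size_t)ix * H] += cp[kh + KH * (kw + KW * c)];
          }
        }
      }
    }
  }
}

static NumericVector make4d(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector make4di(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector dims4(const NumericVector& x, const char* what) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("%s must be a 4-d array", what);
  return d;
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(const NumericVector& x, const NumericVector& w,
                        const Nullable<NumericVector>& bias, int stride,
                        int pad) {
  IntegerVector dx = dims4(x, "x"), dw = dims4(w, "w");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int KH = dw[0], KW = dw[1], Cout = dw[3];
  if (dw[2] != C) stop("channel mismatch in conv2d_fw");
  const int Ho = (H + 2 * pad - KH) / stride + 1;
  const int Wo = (W + 2 * pad - KW) / stride + 1;
  if (Ho <= 0 || Wo <= 0) stop("non-positive conv output size");
  const int K = KH * KW * C, P = Ho * Wo;

  NumericVector y = make4d(Ho, Wo, Cout, N);
  mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  mat col(K, P);
  arma::rowvec bv;
  bool has_b = bias.isNotNull();
  if (has_b) {
    NumericVector b(bias);
    if ((int)b.size() != Cout) stop("bias length mismatch");
    bv = arma::rowvec(b.begin(), Cout);
  }
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C, KH, KW, stride, pad,
               Ho, Wo, col.memptr());
    mat out(y.begin() + (size_t)n * P * Cout, P, Cout, false, true);
    out = col.t() * Wm;
    if (has_b) out.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(const NumericVector& x, const NumericVector& w,
               const NumericVector& gy, int stride, int pad, bool has_bias) {
  IntegerVector dx = dims4(x, "x"), dw = dims4(w, "w"), dg = dims4(gy, "gy");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int KH = dw[0], KW = dw[1], Cout = dw[3];
  const int Ho = dg[0], Wo = dg[1];
  const int K = KH * KW * C, P = Ho * Wo;

  NumericVector gx = make4d(H, W, C, N);
  NumericVector gw = make4d(KH, KW, C, Cout);
  NumericVector gb(Cout);
  mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  mat gWm(gw.begin(), K, Cout, false, true);
  mat col(K, P), gcol(K, P);
  for (int n = 0; n < N; ++n) {
    mat gym(const_cast<double*>(gy.begin()) + (size_t)n * P * Cout, P, Cout,
            false, true);
    // input gradient
    gcol = Wm * gym.t();
    col2im_one(gcol.memptr(), H, W, C, KH, KW, stride, pad, Ho, Wo,
               gx.begin() + (size_t)n * H * W * C);
    // weight gradient
    im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C, KH, KW, stride, pad,
               Ho, Wo, col.memptr());
    gWm += col * gym;
    if (has_bias) {
      arma::rowvec s = arma::sum(gym, 0);
      for (int c = 0; c < Cout; ++c) gb[c] += s(c);
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = ".convt2d_fw")]]
NumericVector convt2d_fw(const NumericVector& x, const NumericVector& w,
                         const Nullable<NumericVector>& bias, int stride,
                         int pad) {
  IntegerVector dx = dims4(x, "x"), dw = dims4(w, "w");
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int KH = dw[0], KW = dw[1], Cout = dw[2];
  if (dw[3] != Cin) stop("channel mismatch in convt2d_fw");
  const int Ho = (H - 1) * stride - 2 * pad + KH;
  const int Wo = (W - 1) * stride - 2 * pad + KW;
  if (Ho <= 0 || Wo <= 0) stop("non-positive convt output size");
  const int K = KH * KW * Cout, P = H * W;

  NumericVector y = make4d(Ho, Wo, Cout, N);
  mat Wm(const_cast<double*>(w.begin()), K, Cin, false, true);
  mat gcol(K, P);
  for (int n = 0; n < N; ++n) {
    mat xm(const_cast<double*>(x.begin()) + (size_t)n * P * Cin, P, Cin, false,
           true);
    gcol = Wm * xm.t();
    col2im_one(gcol.memptr(), Ho, Wo, Cout, KH, KW, stride, pad, H, W,
               y.begin() + (size_t)n * Ho * Wo * Cout);
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    if ((int)b.size() != Cout) stop("bias length mismatch");
    double* yp = y.begin();
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < Cout; ++c) {
        double bc = b[c];
        double* p0 = yp + ((size_t)n * Cout + c) * Ho * Wo;
        for (int i = 0; i < Ho * Wo; ++i) p0[i] += bc;
      }
  }
  return y;
}

// [[Rcpp::export(name = ".convt2d_bw")]]
List convt2d_bw(const NumericVector& x, const NumericVector& w,
                const NumericVector& gy, int stride, int pad, bool has_bias) {
  IntegerVector dx = dims4(x, "x"), dw = dims4(w, "w"), dg = dims4(gy, "gy");
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int KH = dw[0], KW = dw[1], Cout = dw[2];
  const int Ho = dg[0], Wo = dg[1];
  const int K = KH * KW * Cout, P = H * W;

  NumericVector gx = make4d(H, W, Cin, N);
  NumericVector gw = make4d(KH, KW, Cout, Cin);
  NumericVector gb(Cout);
  mat Wm(const_cast<double*>(w.begin()), K, Cin, false, true);
  mat gWm(gw.begin(), K, Cin, false, true);
  mat col(K, P);
  for (int n = 0; n < N; ++n) {
    im2col_one(gy.begin() + (size_t)n * Ho * Wo * Cout, Ho, Wo, Cout, KH, KW,
               stride, pad, H, W, col.memptr());
    mat xm(const_cast<double*>(x.begin()) + (size_t)n * P * Cin, P, Cin, false,
           true);
    mat gxm(gx.begin() + (size_t)n * P * Cin, P, Cin, false, true);
    gxm = col.t() * Wm;
    gWm += col * xm;
    if (has_bias) {
      const double* gp = gy.begin() + (size_t)n * Ho * Wo * Cout;
      for (int c = 0; c < Cout; ++c) {
        double s = 0.0;
        const double* p0 = gp + (size_t)c * Ho * Wo;
        for (int i = 0; i < Ho * Wo; ++i) s += p0[i];
        gb[c] += s;
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = ".maxpool_fw")]]
List maxpool_fw(const NumericVector& x, int k, int stride, int pad) {
  IntegerVector dx = dims4(x, "x");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho <= 0 || Wo <= 0) stop("non-positive pool output size");
  NumericVector y = make4d(Ho, Wo, C, N);
  IntegerVector arg = make4di(Ho, Wo, C, N);  // 0-based index into x slice
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      double* yc = y.begin() + ((size_t)n * C + c) * Ho * Wo;
      int* ac = arg.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int ox = 0; ox < Wo; ++ox) {
        for (int oy = 0; oy < Ho; ++oy) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int kw = 0; kw < k; ++kw) {
            int ix = ox * stride - pad + kw;
            if (ix < 0 || ix >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int iy = oy * stride - pad + kh;
              if (iy < 0 || iy >= H) continue;
              double v = xc[iy + (size_t)ix * H];
              if (v > best) {
                best = v;
                besti = iy + ix * H;
              }
            }
          }
          yc[oy + (size_t)Ho * ox] = (besti < 0) ? 0.0 : best;
          ac[oy + (size_t)Ho * ox] = besti;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export(name = ".maxpool_bw")]]
NumericVector maxpool_bw(const NumericVector& gy, const IntegerVector& arg,
                         int H, int W, int C, int N) {
  IntegerVector dg = dims4(gy, "gy");
  const int Ho = dg[0], Wo = dg[1];
  NumericVector gx = make4d(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gc = gy.begin() + ((size_t)n * C + c) * Ho * Wo;
      const int* ac = arg.begin() + ((size_t)n * C + c) * Ho * Wo;
      double* xc = gx.begin() + ((size_t)n * C + c) * H * W;
      for (int i = 0; i < Ho * Wo; ++i)
        if (ac[i] >= 0) xc[ac[i]] += gc[i];
    }
  return gx;
}
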