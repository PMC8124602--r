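// CPU tensor ops for the CNN engine.
//
// Tensors are R arrays in (H, W, C, N) order (column-major, H fastest).
// Convolutions use im2col + GEMM via Armadillo; weight arrays are laid out
// (k, k, C_in, C_out) so that the flattened kernel index order (kh, kw, ci)
// matches the im2col row order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct Dims4 {
  int H, W, C, N;
};

static Dims4 dims4(const NumericVector& x, const char* what) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("%s must be a 4-d (H, W, C, N) array", what);
  Dims4 out = {d[0], d[1], d[2], d[3]};
  return out;
}

static int out_extent(int in, int k, int stride, int pad0, int pad1) {
  return (in + pad0 + pad1 - k) / stride + 1;
}

static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector y((R_xlen_t)a * b * c * d);
  y.attr("dim") = IntegerVector::create(a, b, c, d);
  return y;
}

// fill the im2col matrix (K x Ho*Wo) for one sample
static void im2col(const double* x, int H, int W, int C, int k, int stride,
                   int pt, int pl, int Ho, int Wo, arma::mat& col) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int j = ho + Ho * wo;
      double* cj = col.colptr(j);
      for (int ci = 0; ci < C; ++ci) {
        const double* xc = x + (size_t)H * W * ci;
        for (int dw = 0; dw < k; ++dw) {
          int wi = wo * stride - pl + dw;
          for (int dh = 0; dh < k; ++dh) {
            int hi = ho * stride - pt + dh;
            double v = 0.0;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W) v = xc[hi + (size_t)H * wi];
            cj[dh + k * dw + k * k * ci] = v;
          }
        }
      }
    }
  }
}

static void col2im_add(double* x, int H, int W, int C, int k, int stride,
                       int pt, int pl, int Ho, int Wo, const arma::mat& col) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int j = ho + Ho * wo;
      const double* cj = col.colptr(j);
      for (int ci = 0; ci < C; ++ci) {
        double* xc = x + (size_t)H * W * ci;
        for (int dw = 0; dw < k; ++dw) {
          int wi = wo * stride - pl + dw;
          if (wi < 0 || wi >= W) continue;
          for (int dh = 0; dh < k; ++dh) {
            int hi = ho * stride - pt + dh;
            if (hi < 0 || hi >= H) continue;
            xc[hi + (size_t)H * wi] += cj[dh + k * dw + k * k * ci];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, Nullable<NumericVector> bias,
                        int stride, IntegerVector pad) {
  Dims4 xd = dims4(x, "x");
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("w must be (k, k, C_in, C_out)");
  int k = wd[0], cin = wd[2], cout = wd[3];
  if (wd[1] != k) stop("only square kernels are supported");
  if (cin != xd.C) stop("kernel C_in (%d) does not match input channels (%d)", cin, xd.C);
  int pt = pad[0], pb = pad[1], pl = pad[2], pr = pad[3];
  int Ho = out_extent(xd.H, k, stride, pt, pb);
  int Wo = out_extent(xd.W, k, stride, pl, pr);
  if (Ho < 1 || Wo < 1) stop("convolution output would be empty");

  int K = k * k * cin;
  arma::mat Wm(const_cast<double*>(w.begin()), K, cout, false, true);
  arma::mat col(K, (size_t)Ho * Wo);

  NumericVector y = alloc4(Ho, Wo, cout, xd.N);
  arma::rowvec bv(cout, arma::fill::zeros);
  if (bias.isNotNull()) {
    NumericVector b(bias);
    if ((int)b.size() != cout) stop("bias length mismatch");
    bv = arma::rowvec(b.begin(), cout);
  }

  for (int n = 0; n < xd.N; ++n) {
    const double* xn = x.begin() + (size_t)xd.H * xd.W * xd.C * n;
    im2col(xn, xd.H, xd.W, xd.C, k, stride, pt, pl, Ho, Wo, col);
    arma::mat yn(y.begin() + (size_t)Ho * Wo * cout * n, (size_t)Ho * Wo, cout, false, true);
    yn = col.t() * Wm;
    if (bias.isNotNull()) yn.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
               int stride, IntegerVector pad, bool has_bias) {
  Dims4 xd = dims4(x, "x");
  Dims4 yd = dims4(dy, "dy");
  IntegerVector wd = w.attr("dim");
  int k = wd[0], cin = wd[2], cout = wd[3];
  int pt = pad[0], pl = pad[2];
  int Ho = yd.H, Wo = yd.W;
  int K = k * k * cin;

  arma::mat Wm(const_cast<double*>(w.begin()), K, cout, false, true);
  arma::mat col(K, (size_t)Ho * Wo);
  arma::mat dWm(K, cout, arma::fill::zeros);
  arma::rowvec db(cout, arma::fill::zeros);

  NumericVector dx = alloc4(xd.H, xd.W, xd.C, xd.N);
  for (int n = 0; n < xd.N; ++n) {
    const double* xn = x.begin() + (size_t)xd.H * xd.W * xd.C * n;
    im2col(xn, xd.H, xd.W, xd.C, k, stride, pt, pl, Ho, Wo, col);
    arma::mat dyn(const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * cout * n,
                  (size_t)Ho * Wo, cout, false, true);
    dWm += col * dyn;
    if (has_bias) db += arma::sum(dyn, 0);
    arma::mat dcol = Wm * dyn.t();
    col2im_add(dx.begin() + (size_t)xd.H * xd.W * xd.C * n,
               xd.H, xd.W, xd.C, k, stride, pt, pl, Ho, Wo, dcol);
  }

  NumericVector dwv(dWm.begin(), dWm.end());
  dwv.attr("dim") = IntegerVector::create(k, k, cin, cout);
  List out = List::create(_["dw"] = dwv, _["dx"] = dx);
  if (has_bias) out["db"] = NumericVector(db.begin(), db.end());
  return out;
}

// [[Rcpp::export(name = ".dwconv2d_fw")]]
NumericVector dwconv2d_fw(NumericVector x, NumericVector w, int stride, IntegerVector pad) {
  Dims4 xd = dims4(x, "x");
  IntegerVector wd = w.attr("dim");
  int k = wd[0];
  if (wd[2] != xd.C) stop("depthwise kernel channels mismatch");
  int pt = pad[0], pb = pad[1], pl = pad[2], pr = pad[3];
  int Ho = out_extent(xd.H, k, stride, pt, pb);
  int Wo = out_extent(xd.W, k, stride, pl, pr);

  NumericVector y = alloc4(Ho, Wo, xd.C, xd.N);
  for (int n = 0; n < xd.N; ++n) {
    for (int c = 0; c < xd.C; ++c) {
      const double* xc = x.begin() + (size_t)xd.H * xd.W * (c + (size_t)xd.C * n);
      const double* wc = w.begin() + (size_t)k * k * c;
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)xd.C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = 0.0;
          for (int dw = 0; dw < k; ++dw) {
            int wi = wo * stride - pl + dw;
            if (wi < 0 || wi >= xd.W) continue;
            for (int dh = 0; dh < k; ++dh) {
              int hi = ho * stride - pt + dh;
              if (hi < 0 || hi >= xd.H) continue;
              acc += xc[hi + (size_t)xd.H * wi] * wc[dh + k * dw];
            }
          }
          yc[ho + (size_t)Ho * wo] = acc;
        }
      }
    }
  }
  return y;
}

// Padded cells never win the max (they act as -Inf), matching the usual
// "same"-padding pooling convention; on post-ReLU maps this is also
// indistinguishable from zero padding.
// [[Rcpp::export(name = ".maxpool2d_fw")]]
NumericVector maxpool2d_fw(NumericVector x, int pool, int stride, IntegerVector pad) {
  Dims4 xd = dims4(x, "x");
  int pt = pad[0], pb = pad[1], pl = pad[2], pr = pad[3];
  int Ho = out_extent(xd.H, pool, stride, pt, pb);
  int Wo = out_extent(xd.W, pool, stride, pl, pr);

  NumericVector y = alloc4(Ho, Wo, xd.C, xd.N);
  for (int n = 0; n < xd.N; ++n) {
    for (int c = 0; c < xd.C; ++c) {
      const double* xc = x.begin() + (size_t)xd.H * xd.W * (c + (size_t)xd.C * n);
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)xd.C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double m = R_NegInf;
          for (int dw = 0; dw < pool; ++dw) {
            int wi = wo * stride - pl + dw;
            if (wi < 0 || wi >= xd.W) continue;
            for (int dh = 0; dh < pool; ++dh) {
              int hi = ho * stride - pt + dh;
              if (hi < 0 || hi >= xd.H) continue;
              double v = xc[hi + (size_t)xd.H * wi];
              if (v > m) m = v;
            }
          }
          yc[ho + (size_t)Ho * wo] = m;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".avgpool2d_fw")]]
NumericVector avgpool2d_fw(NumericVector x, int pool, int stride) {
  Dims4 xd = dims4(x, "x");
  int Ho = (xd.H - pool) / stride + 1;
  int Wo = (xd.W - pool) / stride + 1;
  NumericVector y = alloc4(Ho, Wo, xd.C, xd.N);
  double inv = 1.0 / (pool * pool);
  for (int n = 0; n < xd.N; ++n) {
    for (int c = 0; c < xd.C; ++c) {
      const double* xc = x.begin() + (size_t)xd.H * xd.W * (c + (size_t)xd.C * n);
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)xd.C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = 0.0;
          for (int dw = 0; dw < pool; ++dw)
            for (int dh = 0; dh < pool; ++dh)
              acc += xc[(ho * stride + dh) + (size_t)xd.H * (wo * stride + dw)];
          yc[ho + (size_t)Ho * wo] = acc * inv;
        }
      }
    }
  }
  return y;
}

// Bilinear resampling with half-pixel centre alignment:
// src = (dst + 0.5) * in/out - 0.5, clamped at the borders.
// [[Rcpp::export(name = ".resize_bilinear")]]
NumericMatrix resize_bilinear(NumericMatrix x, int oh, int ow) {
  int ih = x.nrow(), iw = x.ncol();
  NumericMatrix y(oh, ow);
  double sh = (double)ih / oh, sw = (double)iw / ow;
  for (int c = 0; c < ow; ++c) {
    double sc = (c + 0.5) * sw - 0.5;
    int c0 = (int)std::floor(sc);
    double fc = sc - c0;
    int c0c = std::min(std::max(c0, 0), iw - 1);
    int c1c = std::min(std::max(c0 + 1, 0), iw - 1);
    for (int r = 0; r < oh; ++r) {
      double sr = (r + 0.5) * sh - 0.5;
      int r0 = (int)std::floor(sr);
      double fr = sr - r0;
      int r0c = std::min(std::max(r0, 0), ih - 1);
      int r1c = std::min(std::max(r0 + 1, 0), ih - 1);
      y(r, c) = (1 - fr) * ((1 - fc) * x(r0c, c0c) + fc * x(r0c, c1c)) +
                fr * ((1 - fc) * x(r1c, c0c) + fc * x(r1c, c1c));
    }
  }
  return y;
}
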