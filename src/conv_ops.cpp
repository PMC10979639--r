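// Low-level tensor kernels for the network layers.
//
// Array layout convention (R column-major):
//   activations  x : dim (H, W, C, N)
//   conv weights w : dim (kh, kw, Cin, Cout)
// im2col row index r = i + kh*(j + kw*c) matches the column-major
// flattening of w, so the per-sample forward is Wmat^T * col.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void get_dims4(const NumericVector& x, int& d0, int& d1, int& d2, int& d3) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array");
  d0 = d[0]; d1 = d[1]; d2 = d[2]; d3 = d[3];
}

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int sh, int sw, int ph, int pw,
                   int Ho, int Wo, arma::mat& M) {
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      double* mcol = M.colptr(oh + Ho * ow);
      int r = 0;
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (size_t)H * W * c;
        for (int j = 0; j < kw; ++j) {
          int iw = ow * sw - pw + j;
          for (int i = 0; i < kh; ++i) {
            int ih = oh * sh - ph + i;
            mcol[r++] = (ih >= 0 && ih < H && iw >= 0 && iw < W)
                          ? xc[ih + H * iw] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_acc(const arma::mat& M, int H, int W, int C,
                       int kh, int kw, int sh, int sw, int ph, int pw,
                       int Ho, int Wo, double* dx) {
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      const double* mcol = M.colptr(oh + Ho * ow);
      int r = 0;
      for (int c = 0; c < C; ++c) {
        double* dxc = dx + (size_t)H * W * c;
        for (int j = 0; j < kw; ++j) {
          int iw = ow * sw - pw + j;
          for (int i = 0; i < kh; ++i) {
            int ih = oh * sh - ph + i;
            if (ih >= 0 && ih < H && iw >= 0 && iw < W)
              dxc[ih + H * iw] += mcol[r];
            ++r;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w, NumericVector b,
                                 int sh, int sw, int ph, int pw) {
  int H, W, C, N, kh, kw, Cin, Cout;
  get_dims4(x, H, W, C, N);
  get_dims4(w, kh, kw, Cin, Cout);
  if (Cin != C) stop("input has %d channels but kernel expects %d", C, Cin);
  int Ho = (H + 2 * ph - kh) / sh + 1;
  int Wo = (W + 2 * pw - kw) / sw + 1;
  if (Ho < 1 || Wo < 1) stop("spatial dims too small for kernel");

  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  arma::colvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  arma::mat M(kh * kw * Cin, Ho * Wo);

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C,
           kh, kw, sh, sw, ph, pw, Ho, Wo, M);
    arma::mat Y = Wm.t() * M;  // Cout x (Ho*Wo)
    Y.each_col() += bv;
    double* yp = y.begin() + (size_t)Ho * Wo * Cout * n;
    for (int c = 0; c < Cout; ++c)
      for (int p = 0; p < Ho * Wo; ++p)
        yp[p + (size_t)Ho * Wo * c] = Y(c, p);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int sh, int sw, int ph, int pw) {
  int H, W, C, N, kh, kw, Cin, Cout, Ho, Wo, Cdy, Ndy;
  get_dims4(x, H, W, C, N);
  get_dims4(w, kh, kw, Cin, Cout);
  get_dims4(dy, Ho, Wo, Cdy, Ndy);
  if (Cin != C || Cdy != Cout || Ndy != N) stop("gradient shape mismatch");

  NumericVector dx(x.size()), dw(w.size()), db(Cout);
  dx.attr("dim") = x.attr("dim");
  dw.attr("dim") = w.attr("dim");
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  arma::mat dWm(dw.begin(), kh * kw * Cin, Cout, false, true);
  arma::colvec dbv(db.begin(), Cout, false, true);
  arma::mat M(kh * kw * Cin, Ho * Wo);

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C,
           kh, kw, sh, sw, ph, pw, Ho, Wo, M);
    // dy sample chunk: (Ho*Wo) x Cout, position index fastest
    arma::mat dYt(const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * Cout * n,
                  Ho * Wo, Cout, false, true);
    dWm += M * dYt;
    dbv += arma::sum(dYt, 0).t();
    arma::mat dcol = Wm * dYt.t();  // (kh*kw*Cin) x (Ho*Wo)
    col2im_acc(dcol, H, W, C, kh, kw, sh, sw, ph, pw, Ho, Wo,
               dx.begin() + (size_t)H * W * C * n);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x, int k, int s, int p) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  int Ho = (H + 2 * p - k) / s + 1;
  int Wo = (W + 2 * p - k) / s + 1;
  if (Ho < 1 || Wo < 1) stop("spatial dims too small for pooling window");

  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector amax(y.size());  // 0-based index into x

  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      size_t base = (size_t)H * W * (c + (size_t)C * n);
      const double* xc = x.begin() + base;
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          double best = R_NegInf;
          int besti = -1;
          for (int j = 0; j < k; ++j) {
            int iw = ow * s - p + j;
            if (iw < 0 || iw >= W) continue;
            for (int i = 0; i < k; ++i) {
              int ih = oh * s - p + i;
              if (ih < 0 || ih >= H) continue;
              double v = xc[ih + H * iw];
              if (v > best) { best = v; besti = ih + H * iw; }
            }
          }
          size_t oi = (size_t)(oh + Ho * (ow + (size_t)Wo * (c + (size_t)C * n)));
          y[oi] = best;
          amax[oi] = (int)(base + besti);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(IntegerVector argmax, IntegerVector xdim,
                                   NumericVector dy) {
  size_t nx = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[argmax[i]] += dy[i];
  return dx;
}

// Average pooling; padded cells count as zeros and the divisor is k*k
// (count_include_pad), which keeps the backward pass a constant fan-out.
// [[Rcpp::export]]
NumericVector cpp_avgpool_forward(NumericVector x, int k, int s, int p) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  int Ho = (H + 2 * p - k) / s + 1;
  int Wo = (W + 2 * p - k) / s + 1;
  if (Ho < 1 || Wo < 1) stop("spatial dims too small for pooling window");

  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  double inv = 1.0 / (k * k);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          double acc = 0.0;
          for (int j = 0; j < k; ++j) {
            int iw = ow * s - p + j;
            if (iw < 0 || iw >= W) continue;
            for (int i = 0; i < k; ++i) {
              int ih = oh * s - p + i;
              if (ih >= 0 && ih < H) acc += xc[ih + H * iw];
            }
          }
          yc[oh + Ho * ow] = acc * inv;
        }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_backward(IntegerVector xdim, int k, int s, int p,
                                   NumericVector dy) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector d = dy.attr("dim");
  int Ho = d[0], Wo = d[1];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  double inv = 1.0 / (k * k);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* dxc = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* dyc = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          double g = dyc[oh + Ho * ow] * inv;
          for (int j = 0; j < k; ++j) {
            int iw = ow * s - p + j;
            if (iw < 0 || iw >= W) continue;
            for (int i = 0; i < k; ++i) {
              int ih = oh * s - p + i;
              if (ih >= 0 && ih < H) dxc[ih + H * iw] += g;
            }
          }
        }
    }
  }
  return dx;
}
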