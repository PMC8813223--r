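// Low-level convolution and pooling kernels for the residual DeepID network.
//
// Layout conventions (all column-major, matching R arrays):
//   activations: [H, W, C, N]   (rows = image rows, fastest dim)
//   weights:     [KH, KW, C_in, C_out]
// Convolutions are implemented as im2col + GEMM; pooling is 2x2/stride-2
// max pooling with argmax bookkeeping for the backward pass.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Gather one image's patches into a (KH*KW*C) x (Ho*Wo) matrix.
static void im2col_one(const double* x, int H, int W, int C,
                       int KH, int KW, int stride, int pad,
                       int Ho, int Wo, arma::mat& cols) {
  for (int ow = 0; ow < Wo; ++ow) {
    const int iw0 = ow * stride - pad;
    for (int oh = 0; oh < Ho; ++oh) {
      const int ih0 = oh * stride - pad;
      double* dst = cols.colptr(oh + (std::size_t)Ho * ow);
      for (int c = 0; c < C; ++c) {
        const double* plane = x + (std::size_t)H * W * c;
        for (int kw = 0; kw < KW; ++kw) {
          const int iw = iw0 + kw;
          const bool wok = (iw >= 0 && iw < W);
          double* d = dst + KH * (kw + KW * c);
          if (!wok) {
            for (int kh = 0; kh < KH; ++kh) d[kh] = 0.0;
            continue;
          }
          const double* src = plane + (std::size_t)H * iw;
          for (int kh = 0; kh < KH; ++kh) {
            const int ih = ih0 + kh;
            d[kh] = (ih >= 0 && ih < H) ? src[ih] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add a (KH*KW*C) x (Ho*Wo) gradient matrix back onto one image.
static void col2im_one(const arma::mat& cols, double* dx,
                       int H, int W, int C,
                       int KH, int KW, int stride, int pad,
                       int Ho, int Wo) {
  for (int ow = 0; ow < Wo; ++ow) {
    const int iw0 = ow * stride - pad;
    for (int oh = 0; oh < Ho; ++oh) {
      const int ih0 = oh * stride - pad;
      const double* src = cols.colptr(oh + (std::size_t)Ho * ow);
      for (int c = 0; c < C; ++c) {
        double* plane = dx + (std::size_t)H * W * c;
        for (int kw = 0; kw < KW; ++kw) {
          const int iw = iw0 + kw;
          if (iw < 0 || iw >= W) continue;
          const double* s = src + KH * (kw + KW * c);
          double* d = plane + (std::size_t)H * iw;
          for (int kh = 0; kh < KH; ++kh) {
            const int ih = ih0 + kh;
            if (ih >= 0 && ih < H) d[ih] += s[kh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch: input has %d, kernel expects %d", C, Cin);
  const int Ho = out_size(H, KH, stride, pad), Wo = out_size(W, KW, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("input %dx%d too small for %dx%d kernel", H, W, KH, KW);

  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  const arma::mat Wm(const_cast<double*>(w.begin()), KH * KW * Cin, Cout, false, true);
  const arma::rowvec bias(const_cast<double*>(b.begin()), Cout, false, true);
  arma::mat cols(KH * KW * Cin, (std::size_t)Ho * Wo);

  const std::size_t xstep = (std::size_t)H * W * C;
  const std::size_t ystep = (std::size_t)Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + n * xstep, H, W, C, KH, KW, stride, pad, Ho, Wo, cols);
    arma::mat Y(y.begin() + n * ystep, (std::size_t)Ho * Wo, Cout, false, true);
    Y = cols.t() * Wm;
    Y.each_row() += bias;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int stride, int pad, bool need_dx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];

  NumericVector dw(w.size());
  dw.attr("dim") = w.attr("dim");
  NumericVector db(Cout);
  NumericVector dx(need_dx ? x.size() : 0);
  if (need_dx) dx.attr("dim") = x.attr("dim");

  arma::mat dWm(dw.begin(), KH * KW * Cin, Cout, false, true);
  arma::rowvec dbv(db.begin(), Cout, false, true);
  const arma::mat Wm(const_cast<double*>(w.begin()), KH * KW * Cin, Cout, false, true);
  arma::mat cols(KH * KW * Cin, (std::size_t)Ho * Wo);
  arma::mat dcols;

  const std::size_t xstep = (std::size_t)H * W * C;
  const std::size_t ystep = (std::size_t)Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + n * xstep, H, W, C, KH, KW, stride, pad, Ho, Wo, cols);
    const arma::mat DY(const_cast<double*>(dy.begin()) + n * ystep,
                       (std::size_t)Ho * Wo, Cout, false, true);
    dWm += cols * DY;
    dbv += arma::sum(DY, 0);
    if (need_dx) {
      dcols = Wm * DY.t();
      col2im_one(dcols, dx.begin() + n * xstep, H, W, C, KH, KW, stride, pad, Ho, Wo);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2; trailing odd row/column dropped.
// idx stores, per pooled element, the 0-based linear offset (h + H*w) of the
// argmax within its input [H, W] plane.
// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;

  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = y.attr("dim");

  const std::size_t planes = (std::size_t)C * N;
  for (std::size_t p = 0; p < planes; ++p) {
    const double* xi = x.begin() + p * (std::size_t)H * W;
    double* yi = y.begin() + p * (std::size_t)Ho * Wo;
    int* ii = idx.begin() + p * (std::size_t)Ho * Wo;
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        const int h0 = 2 * oh, w0 = 2 * ow;
        int best = h0 + H * w0;
        double bv = xi[best];
        const int cand[3] = { h0 + 1 + H * w0, h0 + H * (w0 + 1), h0 + 1 + H * (w0 + 1) };
        for (int k = 0; k < 3; ++k)
          if (xi[cand[k]] > bv) { bv = xi[cand[k]]; best = cand[k]; }
        yi[oh + (std::size_t)Ho * ow] = bv;
        ii[oh + (std::size_t)Ho * ow] = best;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1];

  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * N);
  dx.attr("dim") = xdim;

  const std::size_t planes = (std::size_t)C * N;
  for (std::size_t p = 0; p < planes; ++p) {
    const double* dyi = dy.begin() + p * (std::size_t)Ho * Wo;
    const int* ii = idx.begin() + p * (std::size_t)Ho * Wo;
    double* dxi = dx.begin() + p * (std::size_t)H * W;
    const std::size_t m = (std::size_t)Ho * Wo;
    for (std::size_t q = 0; q < m; ++q) dxi[ii[q]] += dyi[q];
  }
  return dx;
}
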