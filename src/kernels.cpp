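// Low-level tensor kernels for the NN engine.
//
// Tensors are R arrays with dim (N, C, H, W) in R's column-major order, so
// element (n, c, h, w) (0-based) sits at n + N*(c + C*(h + H*w)).
// Convolution weights are matrices of shape (C_out, (C_in/groups)*k*k) whose
// columns are ordered ci + Cing*(ki + k*kj), ki = row (height) offset of the
// kernel tap, kj = column (width) offset.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// im2col for one sample and one group: returns (Cing*k*k) x (Ho*Wo)
static void im2col(const double* x, int N, int C, int H, int W,
                   int n, int c0, int Cing, int k, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  for (int ci = 0; ci < Cing; ++ci) {
    const int c = c0 + ci;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int row = ci + Cing * (ki + k * kj);
        for (int ow = 0; ow < Wo; ++ow) {
          const int iw = ow * stride - pad + kj;
          for (int oh = 0; oh < Ho; ++oh) {
            const int ih = oh * stride - pad + ki;
            double v = 0.0;
            if (ih >= 0 && ih < H && iw >= 0 && iw < W)
              v = x[n + (R_xlen_t)N * (c + (R_xlen_t)C * (ih + (R_xlen_t)H * iw))];
            col(row, oh + Ho * ow) = v;
          }
        }
      }
    }
  }
}

// scatter-add of a column matrix back onto the input gradient
static void col2im(arma::mat& col, double* gx, int N, int C, int H, int W,
                   int n, int c0, int Cing, int k, int stride, int pad,
                   int Ho, int Wo) {
  for (int ci = 0; ci < Cing; ++ci) {
    const int c = c0 + ci;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int row = ci + Cing * (ki + k * kj);
        for (int ow = 0; ow < Wo; ++ow) {
          const int iw = ow * stride - pad + kj;
          if (iw < 0 || iw >= W) continue;
          for (int oh = 0; oh < Ho; ++oh) {
            const int ih = oh * stride - pad + ki;
            if (ih < 0 || ih >= H) continue;
            gx[n + (R_xlen_t)N * (c + (R_xlen_t)C * (ih + (R_xlen_t)H * iw))] +=
              col(row, oh + Ho * ow);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, IntegerVector xdim, NumericMatrix w,
                        int k, int stride, int pad, int groups) {
  const int N = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  const int Cout = w.nrow();
  const int Cing = C / groups, Coutg = Cout / groups;
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  if (Ho < 1 || Wo < 1) stop("convolution output would be empty");
  NumericVector y((R_xlen_t)N * Cout * Ho * Wo);
  arma::mat wm(w.begin(), Cout, w.ncol(), false);
  arma::mat col(Cing * k * k, Ho * Wo);
  double* yp = y.begin();
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(xp, N, C, H, W, n, g * Cing, Cing, k, stride, pad, Ho, Wo, col);
      arma::mat wg = wm.rows(g * Coutg, (g + 1) * Coutg - 1);
      arma::mat out = wg * col;  // Coutg x (Ho*Wo)
      for (int co = 0; co < Coutg; ++co) {
        const int c = g * Coutg + co;
        for (int ow = 0; ow < Wo; ++ow)
          for (int oh = 0; oh < Ho; ++oh)
            yp[n + (R_xlen_t)N * (c + (R_xlen_t)Cout * (oh + (R_xlen_t)Ho * ow))] =
              out(co, oh + Ho * ow);
      }
    }
  }
  y.attr("dim") = IntegerVector::create(N, Cout, Ho, Wo);
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, IntegerVector xdim, NumericVector gy,
               NumericMatrix w, int k, int stride, int pad, int groups) {
  const int N = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  const int Cout = w.nrow();
  const int Cing = C / groups, Coutg = Cout / groups;
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector gx((R_xlen_t)N * C * H * W);
  NumericMatrix gw(Cout, w.ncol());
  arma::mat wm(w.begin(), Cout, w.ncol(), false);
  arma::mat gwm(gw.begin(), Cout, gw.ncol(), false);
  arma::mat col(Cing * k * k, Ho * Wo);
  arma::mat gout(Coutg, Ho * Wo);
  const double* xp = x.begin();
  const double* gyp = gy.begin();
  double* gxp = gx.begin();
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(xp, N, C, H, W, n, g * Cing, Cing, k, stride, pad, Ho, Wo, col);
      for (int co = 0; co < Coutg; ++co) {
        const int c = g * Coutg + co;
        for (int ow = 0; ow < Wo; ++ow)
          for (int oh = 0; oh < Ho; ++oh)
            gout(co, oh + Ho * ow) =
              gyp[n + (R_xlen_t)N * (c + (R_xlen_t)Cout * (oh + (R_xlen_t)Ho * ow))];
      }
      gwm.rows(g * Coutg, (g + 1) * Coutg - 1) += gout * col.t();
      arma::mat wg = wm.rows(g * Coutg, (g + 1) * Coutg - 1);
      arma::mat gcol = wg.t() * gout;
      col2im(gcol, gxp, N, C, H, W, n, g * Cing, Cing, k, stride, pad, Ho, Wo);
    }
  }
  gx.attr("dim") = xdim;
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// [[Rcpp::export(name = ".maxpool_fw")]]
List maxpool_fw(NumericVector x, IntegerVector xdim, int k, int stride, int pad) {
  const int N = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  if (Ho < 1 || Wo < 1) stop("pooling output would be empty");
  NumericVector y((R_xlen_t)N * C * Ho * Wo);
  NumericVector idx((R_xlen_t)N * C * Ho * Wo);  // 1-based linear index into x
  const double* xp = x.begin();
  double* yp = y.begin();
  double* ip = idx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          double best = R_NegInf;
          R_xlen_t bidx = -1;
          for (int kj = 0; kj < k; ++kj) {
            const int iw = ow * stride - pad + kj;
            if (iw < 0 || iw >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int ih = oh * stride - pad + ki;
              if (ih < 0 || ih >= H) continue;
              const R_xlen_t xi =
                n + (R_xlen_t)N * (c + (R_xlen_t)C * (ih + (R_xlen_t)H * iw));
              if (xp[xi] > best) { best = xp[xi]; bidx = xi; }
            }
          }
          const R_xlen_t yi =
            n + (R_xlen_t)N * (c + (R_xlen_t)C * (oh + (R_xlen_t)Ho * ow));
          yp[yi] = best;
          ip[yi] = (double)(bidx + 1);
        }
  y.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bw")]]
NumericVector maxpool_bw(NumericVector gy, NumericVector idx, IntegerVector xdim) {
  NumericVector gx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  double* gxp = gx.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i)
    gxp[(R_xlen_t)idx[i] - 1] += gy[i];
  gx.attr("dim") = xdim;
  return gx;
}

// [[Rcpp::export(name = ".avgpool_fw")]]
NumericVector avgpool_fw(NumericVector x, IntegerVector xdim, int k, int stride,
                         int pad) {
  const int N = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  if (Ho < 1 || Wo < 1) stop("pooling output would be empty");
  NumericVector y((R_xlen_t)N * C * Ho * Wo);
  const double* xp = x.begin();
  double* yp = y.begin();
  const double inv = 1.0 / (k * k);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          double s = 0.0;
          for (int kj = 0; kj < k; ++kj) {
            const int iw = ow * stride - pad + kj;
            if (iw < 0 || iw >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int ih = oh * stride - pad + ki;
              if (ih < 0 || ih >= H) continue;
              s += xp[n + (R_xlen_t)N * (c + (R_xlen_t)C * (ih + (R_xlen_t)H * iw))];
            }
          }
          yp[n + (R_xlen_t)N * (c + (R_xlen_t)C * (oh + (R_xlen_t)Ho * ow))] = s * inv;
        }
  y.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  return y;
}

// [[Rcpp::export(name = ".avgpool_bw")]]
NumericVector avgpool_bw(NumericVector gy, IntegerVector xdim, int k, int stride,
                         int pad) {
  const int N = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector gx((R_xlen_t)N * C * H * W);
  const double* gyp = gy.begin();
  double* gxp = gx.begin();
  const double inv = 1.0 / (k * k);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          const double g =
            gyp[n + (R_xlen_t)N * (c + (R_xlen_t)C * (oh + (R_xlen_t)Ho * ow))] * inv;
          for (int kj = 0; kj < k; ++kj) {
            const int iw = ow * stride - pad + kj;
            if (iw < 0 || iw >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int ih = oh * stride - pad + ki;
              if (ih < 0 || ih >= H) continue;
              gxp[n + (R_xlen_t)N * (c + (R_xlen_t)C * (ih + (R_xlen_t)H * iw))] += g;
            }
          }
        }
  gx.attr("dim") = xdim;
  return gx;
}
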