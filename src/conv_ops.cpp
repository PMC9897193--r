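#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Minimal 2-D convolution / max-pooling primitives for the haplotype
// classifier, implemented as im2col + BLAS gemm. Tensors are R arrays with
// dim (H, W, C, B); weights are F x (C*kH*kW) matrices with row layout
// r = (c*kH + dh)*kW + dw. Everything is deterministic.

namespace {

inline void im2col(const double* x, int H, int W, int C,
                   int kH, int kW, int padH, int padW,
                   int Ho, int Wo, arma::mat& K) {
  // K: (C*kH*kW) x (Ho*Wo); column j = ho + Ho*wo
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int dh = 0; dh < kH; ++dh) {
      for (int dw = 0; dw < kW; ++dw) {
        int r = (c * kH + dh) * kW + dw;
        for (int wo = 0; wo < Wo; ++wo) {
          int w = wo - padW + dw;
          double* Kcol = K.colptr(0) + r;  // stride K.n_rows per column
          if (w < 0 || w >= W) {
            for (int ho = 0; ho < Ho; ++ho) K((size_t)r, (size_t)(ho + Ho * wo)) = 0.0;
            continue;
          }
          (void)Kcol;
          const double* xcw = xc + (size_t)w * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int h = ho - padH + dh;
            K((size_t)r, (size_t)(ho + Ho * wo)) =
                (h < 0 || h >= H) ? 0.0 : xcw[h];
          }
        }
      }
    }
  }
}

inline void col2im_add(const arma::mat& dK, int H, int W, int C,
                       int kH, int kW, int padH, int padW,
                       int Ho, int Wo, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int dh = 0; dh < kH; ++dh) {
      for (int dw = 0; dw < kW; ++dw) {
        int r = (c * kH + dh) * kW + dw;
        for (int wo = 0; wo < Wo; ++wo) {
          int w = wo - padW + dw;
          if (w < 0 || w >= W) continue;
          double* xcw = xc + (size_t)w * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int h = ho - padH + dh;
            if (h >= 0 && h < H) xcw[h] += dK((size_t)r, (size_t)(ho + Ho * wo));
          }
        }
      }
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".convForwardCpp")]]
NumericVector convForwardCpp(NumericVector x, NumericMatrix w, NumericVector bias,
                             int kH, int kW, int padH, int padW) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], B = d[3];
  int F = w.nrow();
  int Ho = H + 2 * padH - kH + 1, Wo = W + 2 * padW - kW + 1;
  arma::mat Wm(w.begin(), F, w.ncol(), false);
  arma::vec bv(bias.begin(), F, false);

  NumericVector y((R_xlen_t)Ho * Wo * F * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, B);
  arma::mat K(C * kH * kW, Ho * Wo);
  for (int b = 0; b < B; ++b) {
    im2col(x.begin() + (size_t)b * H * W * C, H, W, C, kH, kW, padH, padW, Ho, Wo, K);
    arma::mat Y = Wm * K;               // F x (Ho*Wo)
    Y.each_col() += bv;
    double* yb = y.begin() + (size_t)b * Ho * Wo * F;
    // Y(f, j) -> y[ho, wo, f]; j = ho + Ho*wo
    for (int f = 0; f < F; ++f)
      for (int j = 0; j < Ho * Wo; ++j)
        yb[(size_t)f * Ho * Wo + j] = Y((size_t)f, (size_t)j);
  }
  return y;
}

// [[Rcpp::export(name = ".convBackwardCpp")]]
List convBackwardCpp(NumericVector x, NumericMatrix w, NumericVector dy,
                     int kH, int kW, int padH, int padW) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], B = d[3];
  int F = w.nrow();
  int Ho = H + 2 * padH - kH + 1, Wo = W + 2 * padW - kW + 1;
  arma::mat Wm(w.begin(), F, w.ncol(), false);

  NumericVector dx((R_xlen_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  NumericMatrix dwR(F, w.ncol());
  arma::mat dW(dwR.begin(), F, w.ncol(), false);
  NumericVector dbR(F);
  arma::vec db(dbR.begin(), F, false);

  arma::mat K(C * kH * kW, Ho * Wo);
  arma::mat dY(F, Ho * Wo);
  for (int b = 0; b < B; ++b) {
    im2col(x.begin() + (size_t)b * H * W * C, H, W, C, kH, kW, padH, padW, Ho, Wo, K);
    const double* dyb = dy.begin() + (size_t)b * Ho * Wo * F;
    for (int f = 0; f < F; ++f)
      for (int j = 0; j < Ho * Wo; ++j)
        dY((size_t)f, (size_t)j) = dyb[(size_t)f * Ho * Wo + j];
    dW += dY * K.t();
    db += arma::sum(dY, 1);
    arma::mat dK = Wm.t() * dY;
    col2im_add(dK, H, W, C, kH, kW, padH, padW, Ho, Wo,
               dx.begin() + (size_t)b * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dwR, _["db"] = dbR);
}

// 2x2 max pooling with stride 2 (floor division of dims).
// [[Rcpp::export(name = ".maxPoolForwardCpp")]]
List maxPoolForwardCpp(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], B = d[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  IntegerVector arg((R_xlen_t)Ho * Wo * C * B);  // 0-based linear index into x
  arg.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + ((size_t)b * C + c) * H * W;
      size_t base = ((size_t)b * C + c) * H * W;
      double* yp = y.begin() + ((size_t)b * C + c) * Ho * Wo;
      int* ap = arg.begin() + ((size_t)b * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300; int bi = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              int h = 2 * ho + dh, w = 2 * wo + dw;
              int li = h + H * w;
              if (xp[li] > best) { best = xp[li]; bi = li; }
            }
          yp[ho + Ho * wo] = best;
          ap[ho + Ho * wo] = (int)(base + bi);
        }
    }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxPoolBackwardCpp")]]
NumericVector maxPoolBackwardCpp(NumericVector dy, IntegerVector argmax,
                                 IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  int n = dy.size();
  for (int i = 0; i < n; ++i) dx[argmax[i]] += dy[i];
  return dx;
}
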