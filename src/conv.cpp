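// 2D convolution kernels (im2col + GEMM) used by the network layers.
// Array layout follows R's column-major convention throughout:
//   activations  x : H x W x C x N
//   weights      w : k x k x C_in x C_out
// so a (k*k*C_in) x C_out matrix view of `w` needs no copy.  One im2col
// buffer is reused across the batch to stay cache-resident.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Fill columns [n*Ho*Wo, (n+1)*Ho*Wo) of `cols` with patches of image n.
static void im2col_one(const double* x_n, int H, int W, int C, int k,
                       int stride, int pad, int Ho, int Wo, arma::mat& cols,
                       arma::uword col0) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x_n + (std::size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const arma::uword r = ki + k * kj + k * k * c;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          double* dst = cols.memptr() + r +
            cols.n_rows * (col0 + (arma::uword)(Ho * wo));
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho, dst += cols.n_rows) *dst = 0.0;
            continue;
          }
          const double* src = xc + H * wi;
          int hi = -pad + ki; // input row for ho = 0
          for (int ho = 0; ho < Ho; ++ho, dst += cols.n_rows, hi += stride) {
            *dst = (hi < 0 || hi >= H) ? 0.0 : src[hi];
          }
        }
      }
    }
  }
}

static void col2im_one(const arma::mat& dcols, arma::uword col0, int H, int W,
                       int C, int k, int stride, int pad, int Ho, int Wo,
                       double* dx_n) {
  for (int c = 0; c < C; ++c) {
    double* dxc = dx_n + (std::size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const arma::uword r = ki + k * kj + k * k * c;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          const double* src = dcols.memptr() + r +
            dcols.n_rows * (col0 + (arma::uword)(Ho * wo));
          double* dst = dxc + H * wi;
          int hi = -pad + ki;
          for (int ho = 0; ho < Ho; ++ho, src += dcols.n_rows, hi += stride) {
            if (hi >= 0 && hi < H) dst[hi] += *src;
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], F = wd[3];
  if (wd[2] != C) stop("conv2d: input has %d channels, weights expect %d", C, wd[2]);
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  const arma::uword P = (arma::uword)Ho * Wo;

  arma::mat A(const_cast<double*>(w.begin()), (arma::uword)(k * k * C),
              (arma::uword)F, false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), (arma::uword)F, false, true);

  NumericVector y((R_xlen_t)Ho * Wo * F * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);

  arma::mat cols((arma::uword)(k * k * C), P);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (std::size_t)n * H * W * C, H, W, C, k, stride,
               pad, Ho, Wo, cols, 0);
    arma::mat Yn(y.begin() + (std::size_t)n * P * F, P, (arma::uword)F,
                 false, true);
    Yn = cols.t() * A; // dgemm with transposed A-side view, no copy
    Yn.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                     int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], F = wd[3];
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  const arma::uword P = (arma::uword)Ho * Wo;

  arma::mat A(const_cast<double*>(w.begin()), (arma::uword)(k * k * C),
              (arma::uword)F, false, true);

  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw((R_xlen_t)k * k * C * F);
  dw.attr("dim") = wd;
  NumericVector db(F);

  arma::mat dA(dw.begin(), (arma::uword)(k * k * C), (arma::uword)F, false, true);
  arma::rowvec dbv(db.begin(), (arma::uword)F, false, true);

  arma::mat cols((arma::uword)(k * k * C), P);
  arma::mat dcols((arma::uword)(k * k * C), P);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (std::size_t)n * H * W * C, H, W, C, k, stride,
               pad, Ho, Wo, cols, 0);
    arma::mat Gn(const_cast<double*>(dy.begin()) + (std::size_t)n * P * F,
                 P, (arma::uword)F, false, true);
    dA += cols * Gn;
    dbv += arma::sum(Gn, 0);
    dcols = A * Gn.t();
    col2im_one(dcols, 0, H, W, C, k, stride, pad, Ho, Wo,
               dx.begin() + (std::size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
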