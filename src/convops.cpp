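// im2col-based convolution and max-pooling kernels for the image encoder.
// Arrays follow R's column-major layout: images are (H, W, C, N), kernels
// (KH, KW, C, F). The GEMM goes through Armadillo (BLAS).
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill col (KH*KW*C x Ho*Wo) from one image; zero padding.
static void im2col(const double* x, int H, int W, int C, int KH, int KW,
                   int stride, int pad, int Ho, int Wo, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < KW; ++kj) {
      for (int ki = 0; ki < KH; ++ki) {
        int row = ki + KH * (kj + KW * c);
        for (int j = 0; j < Wo; ++j) {
          int wj = j * stride - pad + kj;
          double* dst = col.colptr(0) + row; // strided writes via (row, col)
          if (wj < 0 || wj >= W) {
            for (int i = 0; i < Ho; ++i) col(row, i + Ho * j) = 0.0;
            continue;
          }
          const double* xc = x + (size_t)H * (wj + (size_t)W * c);
          for (int i = 0; i < Ho; ++i) {
            int wi = i * stride - pad + ki;
            col(row, i + Ho * j) = (wi >= 0 && wi < H) ? xc[wi] : 0.0;
          }
          (void)dst;
        }
      }
    }
  }
}

// Scatter-add dcol back into one image's gradient.
static void col2im(const arma::mat& dcol, int H, int W, int C, int KH, int KW,
                   int stride, int pad, int Ho, int Wo, double* dx) {
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < KW; ++kj) {
      for (int ki = 0; ki < KH; ++ki) {
        int row = ki + KH * (kj + KW * c);
        for (int j = 0; j < Wo; ++j) {
          int wj = j * stride - pad + kj;
          if (wj < 0 || wj >= W) continue;
          double* xc = dx + (size_t)H * (wj + (size_t)W * c);
          for (int i = 0; i < Ho; ++i) {
            int wi = i * stride - pad + ki;
            if (wi >= 0 && wi < H) xc[wi] += dcol(row, i + Ho * j);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                        int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int KH = wd[0], KW = wd[1], F = wd[3];
  if (wd[2] != C) stop("channel mismatch between input and kernel");
  int Ho = out_size(H, KH, stride, pad), Wo = out_size(W, KW, stride, pad);
  if (Ho < 1 || Wo < 1) stop("input too small for this convolution");
  NumericVector y(Ho * Wo * (size_t)F * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  arma::mat Wm(const_cast<double*>(w.begin()), KH * KW * C, F, false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), F, false, true);
  arma::mat col(KH * KW * C, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, KH, KW, stride, pad,
           Ho, Wo, col);
    arma::mat Y = col.t() * Wm;          // (Ho*Wo) x F
    Y.each_row() += bv;
    std::copy(Y.begin(), Y.end(), y.begin() + (size_t)Ho * Wo * F * n);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
               int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int KH = wd[0], KW = wd[1], F = wd[3];
  int Ho = yd[0], Wo = yd[1];
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  arma::mat dW(KH * KW * C, F, arma::fill::zeros);
  arma::rowvec db(F, arma::fill::zeros);
  arma::mat Wm(const_cast<double*>(w.begin()), KH * KW * C, F, false, true);
  arma::mat col(KH * KW * C, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    arma::mat dYn(const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * F * n,
                  Ho * Wo, F, false, true);
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, KH, KW, stride, pad,
           Ho, Wo, col);
    dW += col * dYn;
    db += arma::sum(dYn, 0);
    arma::mat dcol = Wm * dYn.t();       // (KH*KW*C) x (Ho*Wo)
    col2im(dcol, H, W, C, KH, KW, stride, pad, Ho, Wo,
           dx.begin() + (size_t)H * W * C * n);
  }
  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
List maxpool_fw(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N); // 1-based linear index into x
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t p = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * (0 + (size_t)W * (c + (size_t)C * n));
      size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bi = 0;
          for (int kj = 0; kj < k; ++kj) {
            int wj = j * stride - pad + kj;
            if (wj < 0 || wj >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int wi = i * stride - pad + ki;
              if (wi < 0 || wi >= H) continue;
              double v = xc[wi + (size_t)H * wj];
              if (v > best) { best = v; bi = base + wi + (size_t)H * wj; }
            }
          }
          // output laid out (Ho, Wo, C, N): position i + Ho*(j + Wo*(c + C*n))
          size_t op = i + (size_t)Ho * (j + (size_t)Wo * (c + (size_t)C * n));
          y[op] = best;
          idx[op] = (int)(bi + 1);
          ++p;
        }
      }
    }
  }
  (void)p;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bw(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}
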