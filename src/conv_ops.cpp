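// Same-padding 2D convolution kernels used by the residual networks.
// Layout follows R's column-major arrays: inputs are (H, W, C, N) numeric
// arrays, weights are (k*k*Cin) x Cout matrices obtained by flattening an
// R array of dim c(k, k, Cin, Cout).  The whole batch is lowered into one
// im2col matrix so the convolution is a single BLAS GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// rows [n*H*W, (n+1)*H*W) of `cols` hold sample n
static void im2col_batch(const double* x, int H, int W, int C, int N,
                         int k, int dil, arma::mat& cols) {
  const int pad = dil * (k - 1) / 2;
  const std::size_t HW = (std::size_t)H * W;
  cols.zeros();
  for (int n = 0; n < N; ++n) {
    const double* xn = x + HW * C * n;
    const std::size_t row0 = HW * n;
    for (int c = 0; c < C; ++c) {
      const double* xc = xn + HW * c;
      for (int kw = 0; kw < k; ++kw) {
        for (int kh = 0; kh < k; ++kh) {
          const int col = kh + k * kw + k * k * c;
          double* dst = cols.colptr(col) + row0;
          const int dh = kh * dil - pad, dw = kw * dil - pad;
          for (int w = 0; w < W; ++w) {
            const int sw = w + dw;
            if (sw < 0 || sw >= W) continue;
            const double* src = xc + (std::size_t)H * sw;
            double* d = dst + (std::size_t)H * w;
            for (int h = 0; h < H; ++h) {
              const int sh = h + dh;
              if (sh >= 0 && sh < H) d[h] = src[sh];
            }
          }
        }
      }
    }
  }
}

static void col2im_batch_add(const arma::mat& cols, int H, int W, int C,
                             int N, int k, int dil, double* x) {
  const int pad = dil * (k - 1) / 2;
  const std::size_t HW = (std::size_t)H * W;
  for (int n = 0; n < N; ++n) {
    double* xn = x + HW * C * n;
    const std::size_t row0 = HW * n;
    for (int c = 0; c < C; ++c) {
      double* xc = xn + HW * c;
      for (int kw = 0; kw < k; ++kw) {
        for (int kh = 0; kh < k; ++kh) {
          const int col = kh + k * kw + k * k * c;
          const double* src0 = cols.colptr(col) + row0;
          const int dh = kh * dil - pad, dw = kw * dil - pad;
          for (int w = 0; w < W; ++w) {
            const int sw = w + dw;
            if (sw < 0 || sw >= W) continue;
            double* dst = xc + (std::size_t)H * sw;
            const double* src = src0 + (std::size_t)H * w;
            for (int h = 0; h < H; ++h) {
              const int sh = h + dh;
              if (sh >= 0 && sh < H) dst[sh] += src[h];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericMatrix w,
                                 NumericVector b, int k, int dil) {
  IntegerVector dims(x.attr("dim"));
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Cout = w.ncol();
  if (w.nrow() != k * k * C) stop("weight shape does not match kernel/channels");
  const std::size_t HW = (std::size_t)H * W;
  NumericVector out(HW * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(w.begin(), w.nrow(), Cout, false);
  arma::mat cols(HW * N, (std::size_t)k * k * C);
  im2col_batch(x.begin(), H, W, C, N, k, dil, cols);
  arma::mat Y = cols * Wm;                      // (N*HW) x Cout
  Y.each_row() += arma::rowvec(b.begin(), Cout, false);
  // Y rows for sample n are contiguous; output wants (H,W,Cout,N)
  for (int n = 0; n < N; ++n) {
    arma::mat Yn = Y.rows(HW * n, HW * (n + 1) - 1);
    std::copy(Yn.begin(), Yn.end(), out.begin() + HW * Cout * n);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericMatrix w,
                         NumericVector dy, int k, int dil,
                         bool compute_dx = true) {
  IntegerVector dims(x.attr("dim"));
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Cout = w.ncol();
  const std::size_t HW = (std::size_t)H * W;
  arma::mat Wm(w.begin(), w.nrow(), Cout, false);
  NumericVector dx(HW * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat cols(HW * N, (std::size_t)k * k * C);
  im2col_batch(x.begin(), H, W, C, N, k, dil, cols);
  arma::mat dY(HW * N, Cout);
  for (int n = 0; n < N; ++n)
    dY.rows(HW * n, HW * (n + 1) - 1) =
      arma::mat(const_cast<double*>(dy.begin()) + HW * Cout * n,
                HW, Cout, false);
  arma::mat dW = cols.t() * dY;
  arma::vec db = arma::sum(dY, 0).t();
  if (compute_dx) {
    arma::mat dcols = dY * Wm.t();
    col2im_batch_add(dcols, H, W, C, N, k, dil, dx.begin());
  }
  return List::create(_["dx"] = dx,
                      _["dw"] = NumericVector(dW.begin(), dW.end()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}
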