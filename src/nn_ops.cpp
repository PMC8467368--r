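// Minimal 2-D convolution primitives for the in-package neural networks.
// Layout: images are H x W x C arrays (column-major, matching R);
// a conv weight is a (Cout x k*k*Cin) matrix whose row r, entry
// c*k*k + ky*k + kx addresses input channel c, kernel row ky, kernel col
// kx. Forward/backward use im2col + GEMM with the patch matrix stored
// (Ho*Wo) x (k*k*Cin) so the inner loops write contiguously; padding is
// zero-fill.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Patch matrix: (Ho*Wo) x (k*k*C); output pixel (i, j) is row j*Ho + i.
static mat im2colT(const cube& x, int k, int stride, int pad, int Ho,
                   int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat col((uword)Ho * Wo, (uword)k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xs = x.slice_memptr(c);
    for (int ky = 0; ky < k; ++ky) {
      for (int kx = 0; kx < k; ++kx) {
        const int r = c * k * k + ky * k + kx;
        double* dst = col.colptr(r);
        for (int j = 0; j < Wo; ++j) {
          const int xj = j * stride + kx - pad;
          if (xj < 0 || xj >= W) continue;
          const double* src = xs + (uword)xj * H;
          double* d = dst + (uword)j * Ho;
          // xi = i*stride + ky - pad must lie in [0, H)
          int i0 = 0;
          while (i0 * stride + ky - pad < 0) ++i0;
          int i1 = Ho;
          while (i1 > i0 && (i1 - 1) * stride + ky - pad >= H) --i1;
          const double* s = src + (uword)(i0 * stride + ky - pad);
          if (stride == 1) {
            for (int i = i0; i < i1; ++i) d[i] = s[i - i0];
          } else {
            for (int i = i0; i < i1; ++i) d[i] = s[(uword)(i - i0) * stride];
          }
        }
      }
    }
  }
  return col;
}

static void col2imT(const mat& col, cube& dx, int k, int stride, int pad) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  for (int c = 0; c < C; ++c) {
    double* xs = dx.slice_memptr(c);
    for (int ky = 0; ky < k; ++ky) {
      for (int kx = 0; kx < k; ++kx) {
        const int r = c * k * k + ky * k + kx;
        const double* src = col.colptr(r);
        for (int j = 0; j < Wo; ++j) {
          const int xj = j * stride + kx - pad;
          if (xj < 0 || xj >= W) continue;
          double* dcol = xs + (uword)xj * H;
          const double* s = src + (uword)j * Ho;
          int i0 = 0;
          while (i0 * stride + ky - pad < 0) ++i0;
          int i1 = Ho;
          while (i1 > i0 && (i1 - 1) * stride + ky - pad >= H) --i1;
          for (int i = i0; i < i1; ++i)
            dcol[(uword)(i * stride + ky - pad)] += s[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv2d_forward(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, int k, int stride, int pad) {
  const int Ho = out_size(x.n_rows, k, stride, pad);
  const int Wo = out_size(x.n_cols, k, stride, pad);
  const int Cout = w.n_rows;
  mat col = im2colT(x, k, stride, pad, Ho, Wo);
  mat out = col * w.t();               // (Ho*Wo) x Cout
  cube y(Ho, Wo, Cout);
  for (int c = 0; c < Cout; ++c) {
    double* dst = y.slice_memptr(c);
    const double* src = out.colptr(c);
    const double bc = b(c);
    for (uword i = 0; i < (uword)Ho * Wo; ++i) dst[i] = src[i] + bc;
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv2d_backward(const arma::cube& x, const arma::mat& w,
                           const arma::cube& dout, int k, int stride,
                           int pad) {
  const int Ho = dout.n_rows, Wo = dout.n_cols, Cout = dout.n_slices;
  mat col = im2colT(x, k, stride, pad, Ho, Wo);
  mat dmat((uword)Ho * Wo, Cout);
  for (int c = 0; c < Cout; ++c)
    std::memcpy(dmat.colptr(c), dout.slice_memptr(c),
                sizeof(double) * (uword)Ho * Wo);
  mat dw = dmat.t() * col;             // Cout x (k*k*Cin)
  vec db = sum(dmat, 0).t();
  mat dcol = dmat * w;                 // (Ho*Wo) x (k*k*Cin)
  cube dx(x.n_rows, x.n_cols, x.n_slices, fill::zeros);
  col2imT(dcol, dx, k, stride, pad);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// Nearest-neighbour 2x upsampling and its adjoint (2x2 block sum).
// [[Rcpp::export]]
arma::cube upsample2_forward(const arma::cube& x) {
  cube y(2 * x.n_rows, 2 * x.n_cols, x.n_slices);
  for (uword c = 0; c < x.n_slices; ++c)
    for (uword j = 0; j < x.n_cols; ++j)
      for (uword i = 0; i < x.n_rows; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube upsample2_backward(const arma::cube& dy) {
  cube dx(dy.n_rows / 2, dy.n_cols / 2, dy.n_slices);
  for (uword c = 0; c < dy.n_slices; ++c)
    for (uword j = 0; j < dx.n_cols; ++j)
      for (uword i = 0; i < dx.n_rows; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}

// Leaky-ReLU forward/gradient (hot path; avoids R's ifelse allocation).
// [[Rcpp::export]]
arma::cube lrelu_forward(const arma::cube& x, double slope) {
  cube y(x.n_rows, x.n_cols, x.n_slices);
  const double* s = x.memptr();
  double* d = y.memptr();
  for (uword i = 0; i < x.n_elem; ++i)
    d[i] = s[i] > 0 ? s[i] : slope * s[i];
  return y;
}

// [[Rcpp::export]]
arma::cube lrelu_backward(const arma::cube& pre, const arma::cube& dy,
                          double slope) {
  cube dx(pre.n_rows, pre.n_cols, pre.n_slices);
  const double* p = pre.memptr();
  const double* g = dy.memptr();
  double* d = dx.memptr();
  for (uword i = 0; i < pre.n_elem; ++i)
    d[i] = p[i] > 0 ? g[i] : slope * g[i];
  return dx;
}
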