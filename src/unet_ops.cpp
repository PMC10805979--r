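// Minimal 2D CNN kernels for the slice-wise U-Net: same-padding
// convolution via im2col + GEMM, 2x2 max-pooling and nearest-neighbour
// upsampling, each with its backward pass. Arrays use the R column-major
// layout (H, W, C, N).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C, int k,
                   arma::mat& M) {
  int pad = k / 2;
  for (int c = 0; c < C; ++c) {
    const double* plane = x + (size_t)H * W * c;
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        int q = ki + k * (kj + k * c);
        double* col = M.colptr(q);
        int di = ki - pad, dj = kj - pad;
        for (int j = 0; j < W; ++j) {
          int js = j + dj;
          double* dst = col + (size_t)H * j;
          if (js < 0 || js >= W) {
            std::fill(dst, dst + H, 0.0);
            continue;
          }
          const double* src = plane + (size_t)H * js;
          for (int i = 0; i < H; ++i) {
            int is = i + di;
            dst[i] = (is < 0 || is >= H) ? 0.0 : src[is];
          }
        }
      }
  }
}

static void col2im_add(const arma::mat& M, int H, int W, int C, int k,
                       double* dx) {
  int pad = k / 2;
  for (int c = 0; c < C; ++c) {
    double* plane = dx + (size_t)H * W * c;
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        int q = ki + k * (kj + k * c);
        const double* col = M.colptr(q);
        int di = ki - pad, dj = kj - pad;
        for (int j = 0; j < W; ++j) {
          int js = j + dj;
          if (js < 0 || js >= W) continue;
          const double* src = col + (size_t)H * j;
          double* dst = plane + (size_t)H * js;
          for (int i = 0; i < H; ++i) {
            int is = i + di;
            if (is >= 0 && is < H) dst[is] += src[i];
          }
        }
      }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  NumericVector y((R_xlen_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout,
               false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  arma::mat M((size_t)H * W, (size_t)k * k * Cin);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (R_xlen_t)H * W * Cin * n, H, W, Cin, k, M);
    arma::mat Y = M * Wm;
    Y.each_row() += bv;
    std::copy(Y.begin(), Y.end(), y.begin() + (R_xlen_t)H * W * Cout * n);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  NumericVector dx((R_xlen_t)H * W * Cin * N);
  dx.attr("dim") = xd;
  NumericVector dw((R_xlen_t)k * k * Cin * Cout);
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout,
               false, true);
  arma::mat dWm(dw.begin(), (size_t)k * k * Cin, Cout, false, true);
  arma::rowvec dbv(db.begin(), Cout, false, true);
  arma::mat M((size_t)H * W, (size_t)k * k * Cin);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (R_xlen_t)H * W * Cin * n, H, W, Cin, k, M);
    arma::mat dY(const_cast<double*>(dy.begin()) +
                 (R_xlen_t)H * W * Cout * n, (size_t)H * W, Cout, false,
                 true);
    dWm += M.t() * dY;
    dbv += arma::sum(dY, 0);
    arma::mat dM = dY * Wm.t();
    col2im_add(dM, H, W, Cin, k, dx.begin() + (R_xlen_t)H * W * Cin * n);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());
  const double* src = x.begin();
  double* dst = y.begin();
  R_xlen_t p = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      R_xlen_t base = (R_xlen_t)H * W * ((R_xlen_t)C * n + c);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i, ++p) {
          R_xlen_t best = base + (R_xlen_t)2 * i + (R_xlen_t)H * 2 * j;
          double bv = src[best];
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              R_xlen_t q = base + (R_xlen_t)(2 * i + di) +
                           (R_xlen_t)H * (2 * j + dj);
              if (src[q] > bv) { bv = src[q]; best = q; }
            }
          dst[p] = bv;
          idx[p] = (int)best;
        }
    }
  // column-major fill above walks (i,j) inside (c,n): matches (Ho,Wo,C,N)
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector dy,
                               IntegerVector xdim) {
  R_xlen_t nx = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  for (R_xlen_t p = 0; p < dy.size(); ++p) dx[idx[p]] += dy[p];
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((R_xlen_t)4 * H * W * C * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, N);
  const double* src = x.begin();
  double* dst = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      R_xlen_t bs = (R_xlen_t)H * W * ((R_xlen_t)C * n + c);
      R_xlen_t bd = (R_xlen_t)4 * H * W * ((R_xlen_t)C * n + c);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          double v = src[bs + i + (R_xlen_t)H * j];
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di)
              dst[bd + (2 * i + di) + (R_xlen_t)2 * H * (2 * j + dj)] = v;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  int H2 = yd[0], W2 = yd[1], C = yd[2], N = yd[3];
  int H = H2 / 2, W = W2 / 2;
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* src = dy.begin();
  double* dst = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      R_xlen_t bs = (R_xlen_t)H2 * W2 * ((R_xlen_t)C * n + c);
      R_xlen_t bd = (R_xlen_t)H * W * ((R_xlen_t)C * n + c);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          double acc = 0.0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di)
              acc += src[bs + (2 * i + di) + (R_xlen_t)H2 * (2 * j + dj)];
          dst[bd + i + (R_xlen_t)H * j] = acc;
        }
    }
  return dx;
}
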