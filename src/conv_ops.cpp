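// Stride-1 2-D convolution (optionally dilated), 2x2 max pooling, and their
// adjoints. Feature maps are H x W x C cubes; kernels are (k*k*Cin) x Cout
// matrices whose row index runs ki fastest, then kj, then cin — the same
// vectorisation as an R array of dim c(k, k, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// im2col with zero padding; output pixel (i, j) reads input
// (i - pad + ki*dil, j - pad + kj*dil).
static mat im2col(const cube& x, int k, int pad, int dil,
                  int& Ho, int& Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int span = dil * (k - 1) + 1;
  Ho = H + 2 * pad - span + 1;
  Wo = W + 2 * pad - span + 1;
  if (Ho < 1 || Wo < 1)
    Rcpp::stop("input (%dx%d) too small for kernel span %d with padding %d",
               H, W, span, pad);
  mat M(Ho * (size_t)Wo, (size_t)k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const size_t col = ki + (size_t)k * kj + (size_t)k * k * c;
        for (int j = 0; j < Wo; ++j) {
          const int sj = j - pad + kj * dil;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int si = i - pad + ki * dil;
            if (si < 0 || si >= H) continue;
            M(i + (size_t)Ho * j, col) = x(si, sj, c);
          }
        }
      }
  return M;
}

// adjoint of im2col: scatter-add columns back onto the padded lattice
static cube col2im(const mat& M, int H, int W, int C, int k, int pad,
                   int dil, int Ho, int Wo) {
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const size_t col = ki + (size_t)k * kj + (size_t)k * k * c;
        for (int j = 0; j < Wo; ++j) {
          const int sj = j - pad + kj * dil;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int si = i - pad + ki * dil;
            if (si < 0 || si >= H) continue;
            x(si, sj, c) += M(i + (size_t)Ho * j, col);
          }
        }
      }
  return x;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, int k, int pad, int dil) {
  if ((size_t)k * k * x.n_slices != w.n_rows)
    Rcpp::stop("kernel expects %d input values per pixel but got %d",
               (int)w.n_rows, (int)(k * k * x.n_slices));
  int Ho, Wo;
  mat M = im2col(x, k, pad, dil, Ho, Wo);
  mat y = M * w;
  y.each_row() += b.t();
  cube out(Ho, Wo, w.n_cols);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& w,
                          const arma::cube& dy, int k, int pad, int dil) {
  int Ho, Wo;
  mat M = im2col(x, k, pad, dil, Ho, Wo);
  const mat dyM(const_cast<double*>(dy.memptr()),
                (size_t)Ho * Wo, dy.n_slices, false, true);
  mat dw = M.t() * dyM;
  vec db = sum(dyM, 0).t();
  mat dxM = dyM * w.t();
  cube dx = col2im(dxM, x.n_rows, x.n_cols, x.n_slices, k, pad, dil, Ho, Wo);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// 2x2/stride-2 max pooling; records the winning offset (0..3, column-major
// within each window) for the backward pass.
// [[Rcpp::export]]
Rcpp::List cpp_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2)
    Rcpp::stop("max pooling needs even spatial dims, got %dx%d; pad inputs to a multiple of 16", H, W);
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  icube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = x(2 * i, 2 * j, c);
        int arg = 0;
        const double v1 = x(2 * i + 1, 2 * j, c);
        if (v1 > best) { best = v1; arg = 1; }
        const double v2 = x(2 * i, 2 * j + 1, c);
        if (v2 > best) { best = v2; arg = 2; }
        const double v3 = x(2 * i + 1, 2 * j + 1, c);
        if (v3 > best) { best = v3; arg = 3; }
        y(i, j, c) = best;
        idx(i, j, c) = arg;
      }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::cube& dy, const arma::icube& idx) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  cube dx(2 * Ho, 2 * Wo, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const int a = idx(i, j, c);
        dx(2 * i + (a & 1), 2 * j + (a >> 1), c) += dy(i, j, c);
      }
  return dx;
}
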