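// Batched 1-D convolution kernels on time-major matrices.
//
// A batch of C-channel signals of length L is stored as a (B*L) x C matrix
// whose row (t-1)*B + b holds sample t of batch element b. Convolution is a
// single BLAS product of the gathered im2col matrix with the weight matrix;
// the gather/scatter block copies are done here so the R level never
// allocates the large intermediates.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat pad_tm(const mat& M, int B, int pad) {
  if (pad == 0) return M;
  const int L = M.n_rows / B;
  mat Mpad(B * (L + 2 * pad), M.n_cols, fill::zeros);
  Mpad.rows(pad * B, pad * B + M.n_rows - 1) = M;
  return Mpad;
}

// im2col: G columns are ordered offset-major to match the (K*Cin) x Cout
// weight layout (offset k block holds Cin columns).
static mat gather_all(const mat& Mpad, int B, int K, int stride, int Lout) {
  const int Cin = Mpad.n_cols;
  mat G(B * Lout, (size_t)K * Cin);
  for (int k = 0; k < K; ++k) {
    for (int c = 0; c < Cin; ++c) {
      double* dst = G.colptr((size_t)k * Cin + c);
      const double* src = Mpad.colptr(c);
      for (int t = 0; t < Lout; ++t) {
        std::memcpy(dst + (size_t)t * B, src + (size_t)(stride * t + k) * B,
                    sizeof(double) * B);
      }
    }
  }
  return G;
}

// [[Rcpp::export]]
arma::mat cpp_conv1d_forward(const arma::mat& M, const arma::mat& W,
                             const arma::vec& b, int B, int K, int stride,
                             int pad) {
  const int L = M.n_rows / B;
  const int Lout = (L + 2 * pad - K) / stride + 1;
  mat Mpad = pad_tm(M, B, pad);
  mat G = gather_all(Mpad, B, K, stride, Lout);
  mat out = G * W;
  out.each_row() += b.t();
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_backward(const arma::mat& M, const arma::mat& W,
                               const arma::mat& dOut, int B, int K,
                               int stride, int pad) {
  const int L = M.n_rows / B;
  const int Lout = (L + 2 * pad - K) / stride + 1;
  const int Cin = M.n_cols;
  mat Mpad = pad_tm(M, B, pad);
  mat G = gather_all(Mpad, B, K, stride, Lout);
  mat dW = G.t() * dOut;
  vec db = sum(dOut, 0).t();
  mat dG = dOut * W.t();
  mat dMpad(Mpad.n_rows, Cin, fill::zeros);
  // scatter-add; row indices within one offset are distinct
  for (int k = 0; k < K; ++k) {
    for (int c = 0; c < Cin; ++c) {
      double* dst = dMpad.colptr(c);
      const double* src = dG.colptr((size_t)k * Cin + c);
      for (int t = 0; t < Lout; ++t) {
        double* d = dst + (size_t)(stride * t + k) * B;
        const double* s = src + (size_t)t * B;
        for (int i = 0; i < B; ++i) d[i] += s[i];
      }
    }
  }
  mat dM = (pad == 0) ? std::move(dMpad)
                      : mat(dMpad.rows(pad * B, pad * B + M.n_rows - 1));
  return Rcpp::List::create(Rcpp::Named("dM") = dM,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Rectifier returning the clipped output and the activation mask.
// [[Rcpp::export]]
Rcpp::List cpp_relu_forward(const Rcpp::NumericMatrix& X) {
  const R_xlen_t n = X.size();
  Rcpp::NumericMatrix out(X.nrow(), X.ncol());
  Rcpp::LogicalMatrix mask(X.nrow(), X.ncol());
  const double* px = X.begin();
  double* po = out.begin();
  int* pm = LOGICAL(mask);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (px[i] > 0) { po[i] = px[i]; pm[i] = 1; } else { po[i] = 0; pm[i] = 0; }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("mask") = mask);
}
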