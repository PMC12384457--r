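// Compiled kernels for the temporal convolutions, the only compute-heavy
// primitives in the network. Layout convention: activations are R x T
// matrices whose rows are independent 1-D series (trials/electrodes/maps
// stacked); convolution runs along columns (time).
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// im2col patch matrix of the zero-padded input: K x (R*T), column (r,t)
// holding Xpad(r, t .. t+K-1).
static mat im2col_rows(const mat& X, int K, int pad_left) {
  int R = X.n_rows, T = X.n_cols;
  mat Xp(R, T + K - 1, fill::zeros);
  Xp.cols(pad_left, pad_left + T - 1) = X;
  mat cols(K, (size_t)R * T);
  for (int t = 0; t < T; ++t) {
    for (int r = 0; r < R; ++r) {
      double* dst = cols.colptr((size_t)t * R + r);
      for (int k = 0; k < K; ++k) dst[k] = Xp(r, t + k);
    }
  }
  return cols;
}

// Shared-filter 1-D convolution ("same"-style with explicit left pad).
// X: R x T, W: F x K. out: (F*R) x T with out[(f-1)*R + r, t] =
//   sum_k W(f,k) * Xpad(r, t+k-1), Xpad zero-padded by pad_left on the left
//   and K-1-pad_left on the right. Computed as one GEMM over the im2col
//   patch matrix.
// [[Rcpp::export]]
arma::mat conv1d_rows_fwd(const arma::mat& X, const arma::mat& W, int pad_left) {
  int R = X.n_rows, T = X.n_cols, F = W.n_rows, K = W.n_cols;
  mat cols = im2col_rows(X, K, pad_left);
  mat Y = W * cols;                       // F x (R*T), column (r,t)
  mat out(F * R, T);
  for (int t = 0; t < T; ++t)
    for (int r = 0; r < R; ++r) {
      const double* src = Y.colptr((size_t)t * R + r);
      for (int f = 0; f < F; ++f) out(f * R + r, t) = src[f];
    }
  return out;
}

// Gradients of conv1d_rows_fwd. dOut: (F*R) x T. Returns dW (F x K) and
// dX (R x T).
// [[Rcpp::export]]
Rcpp::List conv1d_rows_bwd(const arma::mat& X, const arma::mat& W,
                           const arma::mat& dOut, int pad_left) {
  int R = X.n_rows, T = X.n_cols, F = W.n_rows, K = W.n_cols;
  // regroup dOut into F x (R*T) with column (r,t)
  mat dY(F, (size_t)R * T);
  for (int t = 0; t < T; ++t)
    for (int r = 0; r < R; ++r) {
      double* dst = dY.colptr((size_t)t * R + r);
      for (int f = 0; f < F; ++f) dst[f] = dOut(f * R + r, t);
    }
  mat cols = im2col_rows(X, K, pad_left);
  mat dW = dY * cols.t();                 // F x K
  mat dcols = W.t() * dY;                 // K x (R*T)
  mat dXp(R, T + K - 1, fill::zeros);
  for (int t = 0; t < T; ++t)
    for (int r = 0; r < R; ++r) {
      const double* src = dcols.colptr((size_t)t * R + r);
      for (int k = 0; k < K; ++k) dXp(r, t + k) += src[k];
    }
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("dX") = dXp.cols(pad_left, pad_left + T - 1));
}

// Elementwise ELU and its derivative (y is the forward output).
// [[Rcpp::export]]
arma::mat elu_cpp(const arma::mat& X) {
  mat Y = X;
  Y.for_each([](double& v) { if (v < 0) v = std::exp(v) - 1.0; });
  return Y;
}

// [[Rcpp::export]]
arma::mat elu_grad_cpp(const arma::mat& X, const arma::mat& Y,
                       const arma::mat& dY) {
  mat G = dY;
  const double* x = X.memptr();
  const double* y = Y.memptr();
  double* g = G.memptr();
  for (size_t i = 0; i < G.n_elem; ++i)
    if (x[i] < 0) g[i] *= (y[i] + 1.0);
  return G;
}

// Depthwise (grouped) 1-D convolution: rows are grouped in G contiguous
// blocks of n_per rows; group g is filtered with its own kernel W(g, ).
// X: (G*n_per) x T, W: G x K. Output has the same shape as X.
// [[Rcpp::export]]
arma::mat conv1d_depthwise_fwd(const arma::mat& X, const arma::mat& W,
                               int n_per, int pad_left) {
  int R = X.n_rows, T = X.n_cols, G = W.n_rows, K = W.n_cols;
  if (R != G * n_per) Rcpp::stop("row count does not match group layout");
  mat Xp(R, T + K - 1, fill::zeros);
  Xp.cols(pad_left, pad_left + T - 1) = X;
  mat out(R, T, fill::zeros);
  for (int g = 0; g < G; ++g) {
    for (int k = 0; k < K; ++k) {
      double w = W(g, k);
      if (w == 0.0) continue;
      out.rows(g * n_per, (g + 1) * n_per - 1) +=
        w * Xp.submat(g * n_per, k, (g + 1) * n_per - 1, k + T - 1);
    }
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv1d_depthwise_bwd(const arma::mat& X, const arma::mat& W,
                                const arma::mat& dOut, int n_per, int pad_left) {
  int R = X.n_rows, T = X.n_cols, G = W.n_rows, K = W.n_cols;
  mat Xp(R, T + K - 1, fill::zeros);
  Xp.cols(pad_left, pad_left + T - 1) = X;
  mat dW(G, K, fill::zeros);
  mat dXp(R, T + K - 1, fill::zeros);
  for (int g = 0; g < G; ++g) {
    const mat dog = dOut.rows(g * n_per, (g + 1) * n_per - 1);
    for (int k = 0; k < K; ++k) {
      dW(g, k) = accu(dog % Xp.submat(g * n_per, k, (g + 1) * n_per - 1, k + T - 1));
      dXp.submat(g * n_per, k, (g + 1) * n_per - 1, k + T - 1) += W(g, k) * dog;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("dX") = dXp.cols(pad_left, pad_left + T - 1));
}
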