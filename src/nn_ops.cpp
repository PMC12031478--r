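// Neural kernels for the feature-extraction networks.
//
// Batches are cubes laid out (channels, length, batch); convolutions use
// "same" zero padding with an odd kernel. One FEN block is
// conv1d -> tanh -> batchnorm -> adaptive average pooling; block_fwd_cpp /
// block_bwd_cpp fuse the four stages into one call each, while the
// stage-level primitives stay exported for oracle tests. Hot loops are
// written against raw memory (channel is the fastest-varying index).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// im2col over the whole batch: column (l, s) holds the k input windows.
static void fill_xcol(mat& Xcol, const cube& X, const int k, const int pad) {
  const int c_in = X.n_rows, L = X.n_cols, n = X.n_slices;
  Xcol.zeros();
  for (int s = 0; s < n; ++s) {
    for (int d = 0; d < k; ++d) {
      const int shift = d - pad;  // input column = output column + shift
      const int lo = std::max(0, -shift);
      const int hi = std::min(L, L - shift);
      for (int l = lo; l < hi; ++l) {
        std::memcpy(Xcol.colptr(s * L + l) + d * c_in,
                    X.slice_colptr(s, l + shift), c_in * sizeof(double));
      }
    }
  }
}

static cube conv_fwd(const cube& X, const cube& W, const vec& b) {
  const int c_in = X.n_rows, L = X.n_cols, n = X.n_slices;
  const int c_out = W.n_rows, k = W.n_slices;
  const int pad = (k - 1) / 2;
  mat W2(c_out, c_in * k);
  for (int d = 0; d < k; ++d) W2.cols(d * c_in, (d + 1) * c_in - 1) = W.slice(d);
  mat Xcol(c_in * k, (uword)L * n);
  fill_xcol(Xcol, X, k, pad);
  mat Ym = W2 * Xcol;                       // one gemm for the whole batch
  Ym.each_col() += b;
  return cube(Ym.memptr(), c_out, L, n);    // same column-major layout
}

static void conv_bwd(const cube& X, const cube& W, const cube& dY, cube& dX,
                     cube& dW, vec& db, const bool need_dx) {
  const int c_in = X.n_rows, L = X.n_cols, n = X.n_slices;
  const int c_out = W.n_rows, k = W.n_slices;
  const int pad = (k - 1) / 2;
  mat W2(c_out, c_in * k);
  for (int d = 0; d < k; ++d) W2.cols(d * c_in, (d + 1) * c_in - 1) = W.slice(d);
  mat Xcol(c_in * k, (uword)L * n);
  fill_xcol(Xcol, X, k, pad);
  const mat dYm((double*)dY.memptr(), c_out, (uword)L * n, false, true);
  mat dW2 = dYm * Xcol.t();
  db = sum(dYm, 1);
  if (need_dx) {
    const mat dXcol = W2.t() * dYm;         // (c_in*k, L*n)
    dX.zeros(c_in, L, n);
    for (int s = 0; s < n; ++s) {
      for (int d = 0; d < k; ++d) {
        const int shift = d - pad;
        const int lo = std::max(0, -shift);
        const int hi = std::min(L, L - shift);
        for (int l = lo; l < hi; ++l) {
          double* dst = dX.slice_colptr(s, l + shift);
          const double* src = dXcol.colptr(s * L + l) + d * c_in;
          for (int c = 0; c < c_in; ++c) dst[c] += src[c];
        }
      }
    }
  }
  dW.set_size(c_out, c_in, k);
  for (int d = 0; d < k; ++d) dW.slice(d) = dW2.cols(d * c_in, (d + 1) * c_in - 1);
}

static void tanh_inplace(cube& A) {
  double* p = A.memptr();
  const uword n = A.n_elem;
  for (uword i = 0; i < n; ++i) p[i] = std::tanh(p[i]);
}

// Batch normalization. Population variance; returns xhat and inv for the
// backward pass.
static void bn_fwd(const cube& X, const vec& gamma, const vec& beta,
                   const vec& run_mean, const vec& run_var, const bool training,
                   const double momentum, const double eps, cube& xhat, cube& Y,
                   vec& inv, vec& new_mean, vec& new_var) {
  const int C = X.n_rows;
  const uword ncols = X.n_elem / C;
  const double M = (double)ncols;
  vec mu(C), v(C);
  if (training) {
    mu.zeros();
    v.zeros();
    const double* p = X.memptr();
    for (uword j = 0; j < ncols; ++j) {
      for (int c = 0; c < C; ++c, ++p) {
        mu[c] += *p;
        v[c] += (*p) * (*p);
      }
    }
    mu /= M;
    v = v / M - square(mu);
    new_mean = (1 - momentum) * run_mean + momentum * mu;
    new_var = (1 - momentum) * run_var + momentum * v;
  } else {
    mu = run_mean;
    v = run_var;
    new_mean = run_mean;
    new_var = run_var;
  }
  inv = 1.0 / sqrt(v + eps);
  xhat.set_size(arma::size(X));
  Y.set_size(arma::size(X));
  const double* p = X.memptr();
  double* px = xhat.memptr();
  double* py = Y.memptr();
  for (uword j = 0; j < ncols; ++j) {
    for (int c = 0; c < C; ++c, ++p, ++px, ++py) {
      *px = (*p - mu[c]) * inv[c];
      *py = gamma[c] * (*px) + beta[c];
    }
  }
}

// Backward through batchnorm and the preceding tanh in one pass:
// dA = bn_backward(dB) * (1 - T^2), T the tanh output (= batchnorm input).
static void bn_tanh_bwd(const cube& dB, const cube& xhat, const cube& T,
                        const vec& inv, const vec& gamma, const bool training,
                        cube& dA, vec& dgamma, vec& dbeta) {
  const int C = dB.n_rows;
  const uword ncols = dB.n_elem / C;
  const double M = (double)ncols;
  dgamma.zeros(C);
  dbeta.zeros(C);
  {
    const double* pd = dB.memptr();
    const double* px = xhat.memptr();
    for (uword j = 0; j < ncols; ++j) {
      for (int c = 0; c < C; ++c, ++pd, ++px) {
        dgamma[c] += (*pd) * (*px);
        dbeta[c] += *pd;
      }
    }
  }
  dA.set_size(arma::size(dB));
  double* pa = dA.memptr();
  const double* pd = dB.memptr();
  const double* px = xhat.memptr();
  const double* pt = T.memptr();
  if (training) {
    // dX = inv/M * (M*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat)) with
    // dxhat = gamma*dY, sum(dxhat) = gamma*dbeta, sum(dxhat*xhat) = gamma*dgamma
    for (uword j = 0; j < ncols; ++j) {
      for (int c = 0; c < C; ++c, ++pa, ++pd, ++px, ++pt) {
        const double g = (inv[c] / M) *
            (M * gamma[c] * (*pd) - gamma[c] * dbeta[c] -
             (*px) * gamma[c] * dgamma[c]);
        *pa = g * (1.0 - (*pt) * (*pt));
      }
    }
  } else {
    for (uword j = 0; j < ncols; ++j) {
      for (int c = 0; c < C; ++c, ++pa, ++pd, ++pt) {
        *pa = (*pd) * gamma[c] * inv[c] * (1.0 - (*pt) * (*pt));
      }
    }
  }
}

// Adaptive average pooling: output bin i averages input positions
// [floor(i*L/Lout), ceiling((i+1)*L/Lout)) (0-based; bins may overlap).
static cube pool_fwd(const cube& X, const int L_out) {
  const int C = X.n_rows, L = X.n_cols, n = X.n_slices;
  cube Y(C, L_out, n);
  for (int s = 0; s < n; ++s) {
    for (int i = 0; i < L_out; ++i) {
      const int a = (int)std::floor((double)i * L / L_out);
      const int b = (int)std::ceil((double)(i + 1) * L / L_out);
      const double w = 1.0 / (b - a);
      double* dst = Y.slice_colptr(s, i);
      std::memset(dst, 0, C * sizeof(double));
      for (int l = a; l < b; ++l) {
        const double* src = X.slice_colptr(s, l);
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
      for (int c = 0; c < C; ++c) dst[c] *= w;
    }
  }
  return Y;
}

static cube pool_bwd(const cube& dY, const int L) {
  const int C = dY.n_rows, L_out = dY.n_cols, n = dY.n_slices;
  cube dX(C, L, n, fill::zeros);
  for (int s = 0; s < n; ++s) {
    for (int i = 0; i < L_out; ++i) {
      const int a = (int)std::floor((double)i * L / L_out);
      const int b = (int)std::ceil((double)(i + 1) * L / L_out);
      const double w = 1.0 / (b - a);
      const double* src = dY.slice_colptr(s, i);
      for (int l = a; l < b; ++l) {
        double* dst = dX.slice_colptr(s, l);
        for (int c = 0; c < C; ++c) dst[c] += w * src[c];
      }
    }
  }
  return dX;
}

// ---- exported primitives (oracle-testable stage by stage) ----

// [[Rcpp::export]]
arma::cube conv1d_fwd_cpp(const arma::cube& X, const arma::cube& W,
                          const arma::vec& b) {
  return conv_fwd(X, W, b);
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd_cpp(const arma::cube& X, const arma::cube& W,
                          const arma::cube& dY) {
  cube dX, dW;
  vec db;
  conv_bwd(X, W, dY, dX, dW, db, true);
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List bn_fwd_cpp(const arma::cube& X, const arma::vec& gamma,
                      const arma::vec& beta, const arma::vec& run_mean,
                      const arma::vec& run_var, const bool training,
                      const double momentum, const double eps) {
  cube xhat, Y;
  vec inv, new_mean, new_var;
  bn_fwd(X, gamma, beta, run_mean, run_var, training, momentum, eps, xhat, Y,
         inv, new_mean, new_var);
  return Rcpp::List::create(
      Rcpp::Named("Y") = Y, Rcpp::Named("xhat") = xhat,
      Rcpp::Named("inv") = inv, Rcpp::Named("new_mean") = new_mean,
      Rcpp::Named("new_var") = new_var);
}

// [[Rcpp::export]]
arma::cube pool_fwd_cpp(const arma::cube& X, const int L_out) {
  return pool_fwd(X, L_out);
}

// [[Rcpp::export]]
arma::cube pool_bwd_cpp(const arma::cube& dY, const int L) {
  return pool_bwd(dY, L);
}

// ---- fused FEN block ----

// [[Rcpp::export]]
Rcpp::List block_fwd_cpp(const arma::cube& X, const arma::cube& W,
                         const arma::vec& b, const arma::vec& gamma,
                         const arma::vec& beta, const arma::vec& run_mean,
                         const arma::vec& run_var, const bool training,
                         const double momentum, const double eps,
                         const int L_out) {
  cube A = conv_fwd(X, W, b);
  tanh_inplace(A);                        // A now holds T = tanh(conv(X))
  cube xhat, B;
  vec inv, new_mean, new_var;
  bn_fwd(A, gamma, beta, run_mean, run_var, training, momentum, eps, xhat, B,
         inv, new_mean, new_var);
  const bool pool_id = ((int)B.n_cols == L_out);
  return Rcpp::List::create(
      Rcpp::Named("Y") = pool_id ? B : pool_fwd(B, L_out),
      Rcpp::Named("T") = A, Rcpp::Named("xhat") = xhat,
      Rcpp::Named("inv") = inv, Rcpp::Named("new_mean") = new_mean,
      Rcpp::Named("new_var") = new_var);
}

// [[Rcpp::export]]
Rcpp::List block_bwd_cpp(const arma::cube& dY, const arma::cube& X,
                         const arma::cube& W, const arma::cube& T,
                         const arma::cube& xhat, const arma::vec& inv,
                         const arma::vec& gamma, const bool training,
                         const bool need_dx) {
  const int L = T.n_cols;
  const bool pool_id = ((int)dY.n_cols == L);
  cube dB = pool_id ? dY : pool_bwd(dY, L);
  cube dA;
  vec dgamma, dbeta;
  bn_tanh_bwd(dB, xhat, T, inv, gamma, training, dA, dgamma, dbeta);
  cube dX, dW;
  vec db;
  conv_bwd(X, W, dA, dX, dW, db, need_dx);
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}
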