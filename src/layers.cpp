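// Performance kernels for the 1-D U-Net: convolution, transposed
// convolution, batch normalization and ReLU, forward and backward.
// Tensors are (channels, length, batch) arrays (column-major, channel
// fastest). R memory is aliased, never copied on entry; each convolution
// is a single im2col + GEMM over the whole batch.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::NumericVector;
using Rcpp::IntegerVector;
using Rcpp::List;
using Rcpp::Named;

static cube alias_cube(NumericVector x) {
  IntegerVector d = x.attr("dim");
  return cube(x.begin(), d[0], d[1], d[2], false, true);
}

static NumericVector alloc_tensor(int c, int l, int b) {
  NumericVector out(Rcpp::no_init((R_xlen_t)c * l * b));
  out.attr("dim") = IntegerVector::create(c, l, b);
  return out;
}

static mat flatten_kernel(const cube& W) {
  const uword Cout = W.n_rows, Cin = W.n_cols, K = W.n_slices;
  mat W2(Cout, Cin * K);
  for (uword k = 0; k < K; ++k) {
    W2.cols(k * Cin, k * Cin + Cin - 1) = W.slice(k);
  }
  return W2;
}

// gather all windows of all batch slices into M ((Cin*K) x (Lout*B))
static void im2col_all(const cube& X, mat& M, int K, int stride, int pad,
                       int Lout) {
  const int Cin = X.n_rows, Lin = X.n_cols, B = X.n_slices;
  double* m = M.memptr();
  for (int s = 0; s < B; ++s) {
    const double* x = X.slice_memptr(s);
    double* ms = m + (size_t)s * Lout * Cin * K;
    for (int t = 0; t < Lout; ++t) {
      double* col = ms + (size_t)t * Cin * K;
      const int start = t * stride - pad;
      for (int k = 0; k < K; ++k) {
        const int pos = start + k;
        if (pos >= 0 && pos < Lin) {
          std::memcpy(col + k * Cin, x + (size_t)pos * Cin,
                      Cin * sizeof(double));
        } else {
          std::memset(col + k * Cin, 0, Cin * sizeof(double));
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv1d_fwd_cpp(NumericVector Xv, NumericVector Wv,
                             const arma::vec& b, int stride, int pad) {
  const cube X = alias_cube(Xv);
  const cube W = alias_cube(Wv);
  const int Cin = X.n_rows, Lin = X.n_cols, B = X.n_slices;
  const int Cout = W.n_rows, K = W.n_slices;
  const int Lout = (Lin + 2 * pad - K) / stride + 1;
  mat W2 = flatten_kernel(W);
  mat M(Cin * K, (size_t)Lout * B);
  im2col_all(X, M, K, stride, pad, Lout);
  NumericVector Yv = alloc_tensor(Cout, Lout, B);
  mat Y(Yv.begin(), Cout, (size_t)Lout * B, false, true);
  Y = W2 * M;
  Y.each_col() += b;
  return Yv;
}

// [[Rcpp::export]]
List conv1d_bwd_cpp(NumericVector dYv, NumericVector Xv, NumericVector Wv,
                    int stride, int pad) {
  const cube X = alias_cube(Xv);
  const cube W = alias_cube(Wv);
  const cube dY = alias_cube(dYv);
  const int Cin = X.n_rows, Lin = X.n_cols, B = X.n_slices;
  const int Cout = W.n_rows, K = W.n_slices;
  const int Lout = dY.n_cols;
  mat W2 = flatten_kernel(W);
  mat M(Cin * K, (size_t)Lout * B);
  im2col_all(X, M, K, stride, pad, Lout);
  const mat dY2(const_cast<double*>(dY.memptr()), Cout, (size_t)Lout * B,
                false, true);
  mat dW2 = dY2 * M.t();
  vec db = sum(dY2, 1);
  mat dM = W2.t() * dY2;        // (Cin*K) x (Lout*B)
  NumericVector dXv = alloc_tensor(Cin, Lin, B);
  std::memset(dXv.begin(), 0, sizeof(double) * dXv.size());
  cube dX(dXv.begin(), Cin, Lin, B, false, true);
  const double* dm = dM.memptr();
  for (int s = 0; s < B; ++s) {
    double* dx = dX.slice_memptr(s);
    const double* dms = dm + (size_t)s * Lout * Cin * K;
    for (int t = 0; t < Lout; ++t) {
      const double* col = dms + (size_t)t * Cin * K;
      const int start = t * stride - pad;
      for (int k = 0; k < K; ++k) {
        const int pos = start + k;
        if (pos >= 0 && pos < Lin) {
          double* dst = dx + (size_t)pos * Cin;
          const double* src = col + k * Cin;
          for (int c = 0; c < Cin; ++c) dst[c] += src[c];
        }
      }
    }
  }
  cube dW(Cout, Cin, K);
  for (int k = 0; k < K; ++k) {
    dW.slice(k) = dW2.cols(k * Cin, k * Cin + Cin - 1);
  }
  return List::create(Named("dX") = dXv, Named("dW") = dW,
                      Named("db") = db);
}

// Transposed convolution with kernel == stride (exact upsampling).
// [[Rcpp::export]]
NumericVector convt1d_fwd_cpp(NumericVector Xv, NumericVector Wv,
                              const arma::vec& b, int stride) {
  const cube X = alias_cube(Xv);
  const cube W = alias_cube(Wv);
  const int Cin = X.n_rows, Lin = X.n_cols, B = X.n_slices;
  const int Cout = W.n_rows;
  const mat X2(const_cast<double*>(X.memptr()), Cin, (size_t)Lin * B,
               false, true);
  NumericVector Yv = alloc_tensor(Cout, Lin * stride, B);
  cube Y(Yv.begin(), Cout, Lin * stride, B, false, true);
  mat Yk((size_t)Cout, (size_t)Lin * B);
  for (int k = 0; k < stride; ++k) {
    Yk = W.slice(k) * X2;
    Yk.each_col() += b;
    const double* yk = Yk.memptr();
    for (int s = 0; s < B; ++s) {
      double* y = Y.slice_memptr(s);
      const double* yks = yk + (size_t)s * Lin * Cout;
      for (int t = 0; t < Lin; ++t) {
        std::memcpy(y + (size_t)(t * stride + k) * Cout,
                    yks + (size_t)t * Cout, Cout * sizeof(double));
      }
    }
  }
  return Yv;
}

// [[Rcpp::export]]
List convt1d_bwd_cpp(NumericVector dYv, NumericVector Xv, NumericVector Wv,
                     int stride) {
  const cube X = alias_cube(Xv);
  const cube W = alias_cube(Wv);
  const cube dY = alias_cube(dYv);
  const int Cin = X.n_rows, Lin = X.n_cols, B = X.n_slices;
  const int Cout = W.n_rows;
  const mat X2(const_cast<double*>(X.memptr()), Cin, (size_t)Lin * B,
               false, true);
  cube dW(Cout, Cin, stride);
  vec db(Cout, fill::zeros);
  NumericVector dXv = alloc_tensor(Cin, Lin, B);
  mat dX2(dXv.begin(), Cin, (size_t)Lin * B, false, true);
  dX2.zeros();
  mat dYk((size_t)Cout, (size_t)Lin * B);
  for (int k = 0; k < stride; ++k) {
    double* dk = dYk.memptr();
    for (int s = 0; s < B; ++s) {
      const double* dy = dY.slice_memptr(s);
      double* dks = dk + (size_t)s * Lin * Cout;
      for (int t = 0; t < Lin; ++t) {
        std::memcpy(dks + (size_t)t * Cout,
                    dy + (size_t)(t * stride + k) * Cout,
                    Cout * sizeof(double));
      }
    }
    dW.slice(k) = dYk * X2.t();
    db += sum(dYk, 1);
    dX2 += W.slice(k).t() * dYk;
  }
  return List::create(Named("dX") = dXv, Named("dW") = dW,
                      Named("db") = db);
}

// Batch normalization over (length, batch) per channel.
// [[Rcpp::export]]
List bn_fwd_cpp(NumericVector Xv, const arma::vec& gamma,
                const arma::vec& beta, bool train, const arma::vec& rmean,
                const arma::vec& rvar, double momentum, double eps) {
  const cube X = alias_cube(Xv);
  const int C = X.n_rows;
  const size_t ncol = (size_t)X.n_cols * X.n_slices;
  const double m = double(ncol);
  const double* x = X.memptr();
  vec mu(C), v(C);
  if (train) {
    mu.zeros(); v.zeros();
    double* mp = mu.memptr();
    for (size_t j = 0; j < ncol; ++j) {
      const double* col = x + j * C;
      for (int c = 0; c < C; ++c) mp[c] += col[c];
    }
    mu /= m;
    double* vp = v.memptr();
    for (size_t j = 0; j < ncol; ++j) {
      const double* col = x + j * C;
      for (int c = 0; c < C; ++c) {
        const double d = col[c] - mp[c];
        vp[c] += d * d;
      }
    }
    v /= m;
  } else {
    mu = rmean;
    v = rvar;
  }
  vec inv = 1.0 / sqrt(v + eps);
  NumericVector xhatv = alloc_tensor(X.n_rows, X.n_cols, X.n_slices);
  NumericVector Yv = alloc_tensor(X.n_rows, X.n_cols, X.n_slices);
  double* xh = xhatv.begin();
  double* y = Yv.begin();
  const double* mp = mu.memptr();
  const double* ip = inv.memptr();
  const double* gp = gamma.memptr();
  const double* bp = beta.memptr();
  for (size_t j = 0; j < ncol; ++j) {
    const double* col = x + j * C;
    double* xcol = xh + j * C;
    double* ycol = y + j * C;
    for (int c = 0; c < C; ++c) {
      const double h = (col[c] - mp[c]) * ip[c];
      xcol[c] = h;
      ycol[c] = gp[c] * h + bp[c];
    }
  }
  vec new_mean = rmean, new_var = rvar;
  if (train) {
    new_mean = (1.0 - momentum) * rmean + momentum * mu;
    new_var = (1.0 - momentum) * rvar + momentum * v;
  }
  return List::create(Named("out") = Yv, Named("xhat") = xhatv,
                      Named("inv") = inv, Named("new_mean") = new_mean,
                      Named("new_var") = new_var);
}

// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector dYv, NumericVector xhatv,
                const arma::vec& inv, const arma::vec& gamma, bool train) {
  const cube dY = alias_cube(dYv);
  const int C = dY.n_rows;
  const size_t ncol = (size_t)dY.n_cols * dY.n_slices;
  const double m = double(ncol);
  const double* dy = dY.memptr();
  vec dgamma(C, fill::zeros), dbeta(C, fill::zeros);
  NumericVector dXv = alloc_tensor(dY.n_rows, dY.n_cols, dY.n_slices);
  double* dx = dXv.begin();
  const double* gp = gamma.memptr();
  const double* ip = inv.memptr();
  if (!train) {
    for (size_t j = 0; j < ncol; ++j) {
      const double* dcol = dy + j * C;
      double* xcol = dx + j * C;
      for (int c = 0; c < C; ++c) xcol[c] = dcol[c] * gp[c] * ip[c];
    }
    return List::create(Named("dX") = dXv, Named("dgamma") = dgamma,
                        Named("dbeta") = dbeta);
  }
  const cube xhat = alias_cube(xhatv);
  const double* xhp = xhat.memptr();
  double* dgp = dgamma.memptr();
  double* dbp = dbeta.memptr();
  for (size_t j = 0; j < ncol; ++j) {
    const double* dcol = dy + j * C;
    const double* xcol = xhp + j * C;
    for (int c = 0; c < C; ++c) {
      dgp[c] += dcol[c] * xcol[c];
      dbp[c] += dcol[c];
    }
  }
  vec mean_dxhat = (gamma % dbeta) / m;
  vec mean_dxhat_xhat = (gamma % dgamma) / m;
  const double* m1 = mean_dxhat.memptr();
  const double* m2 = mean_dxhat_xhat.memptr();
  for (size_t j = 0; j < ncol; ++j) {
    const double* dcol = dy + j * C;
    const double* xcol = xhp + j * C;
    double* xo = dx + j * C;
    for (int c = 0; c < C; ++c) {
      xo[c] = (dcol[c] * gp[c] - m1[c] - xcol[c] * m2[c]) * ip[c];
    }
  }
  return List::create(Named("dX") = dXv, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(NumericVector Xv) {
  NumericVector Yv(Rcpp::no_init(Xv.size()));
  Yv.attr("dim") = Xv.attr("dim");
  const double* x = Xv.begin();
  double* y = Yv.begin();
  const R_xlen_t n = Xv.size();
  for (R_xlen_t i = 0; i < n; ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  return Yv;
}

// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector dYv, NumericVector Yout) {
  NumericVector dXv(Rcpp::no_init(dYv.size()));
  dXv.attr("dim") = dYv.attr("dim");
  const double* dy = dYv.begin();
  const double* y = Yout.begin();
  double* dx = dXv.begin();
  const R_xlen_t n = dYv.size();
  for (R_xlen_t i = 0; i < n; ++i) dx[i] = y[i] > 0 ? dy[i] : 0.0;
  return dXv;
}

// Fused batchnorm + ReLU (one output tensor, one pass).
// [[Rcpp::export]]
List bnrelu_fwd_cpp(NumericVector Xv, const arma::vec& gamma,
                    const arma::vec& beta, bool train,
                    const arma::vec& rmean, const arma::vec& rvar,
                    double momentum, double eps) {
  const cube X = alias_cube(Xv);
  const int C = X.n_rows;
  const size_t ncol = (size_t)X.n_cols * X.n_slices;
  const double m = double(ncol);
  const double* x = X.memptr();
  vec mu(C), v(C);
  if (train) {
    mu.zeros(); v.zeros();
    double* mp = mu.memptr();
    for (size_t j = 0; j < ncol; ++j) {
      const double* col = x + j * C;
      for (int c = 0; c < C; ++c) mp[c] += col[c];
    }
    mu /= m;
    double* vp = v.memptr();
    for (size_t j = 0; j < ncol; ++j) {
      const double* col = x + j * C;
      for (int c = 0; c < C; ++c) {
        const double d = col[c] - mp[c];
        vp[c] += d * d;
      }
    }
    v /= m;
  } else {
    mu = rmean;
    v = rvar;
  }
  vec inv = 1.0 / sqrt(v + eps);
  NumericVector xhatv = alloc_tensor(X.n_rows, X.n_cols, X.n_slices);
  NumericVector Yv = alloc_tensor(X.n_rows, X.n_cols, X.n_slices);
  double* xh = xhatv.begin();
  double* y = Yv.begin();
  const double* mp = mu.memptr();
  const double* ip = inv.memptr();
  const double* gp = gamma.memptr();
  const double* bp = beta.memptr();
  for (size_t j = 0; j < ncol; ++j) {
    const double* col = x + j * C;
    double* xcol = xh + j * C;
    double* ycol = y + j * C;
    for (int c = 0; c < C; ++c) {
      const double h = (col[c] - mp[c]) * ip[c];
      xcol[c] = h;
      const double o = gp[c] * h + bp[c];
      ycol[c] = o > 0 ? o : 0.0;
    }
  }
  vec new_mean = rmean, new_var = rvar;
  if (train) {
    new_mean = (1.0 - momentum) * rmean + momentum * mu;
    new_var = (1.0 - momentum) * rvar + momentum * v;
  }
  return List::create(Named("out") = Yv, Named("xhat") = xhatv,
                      Named("inv") = inv, Named("new_mean") = new_mean,
                      Named("new_var") = new_var);
}

// [[Rcpp::export]]
List bnrelu_bwd_cpp(NumericVector dYv, NumericVector outv,
                    NumericVector xhatv, const arma::vec& inv,
                    const arma::vec& gamma, bool train) {
  const cube dY = alias_cube(dYv);
  const int C = dY.n_rows;
  const size_t ncol = (size_t)dY.n_cols * dY.n_slices;
  const double m = double(ncol);
  const double* dy = dY.memptr();
  const double* out = outv.begin();
  vec dgamma(C, fill::zeros), dbeta(C, fill::zeros);
  NumericVector dXv = alloc_tensor(dY.n_rows, dY.n_cols, dY.n_slices);
  double* dx = dXv.begin();
  const double* gp = gamma.memptr();
  const double* ip = inv.memptr();
  if (!train) {
    for (size_t j = 0; j < ncol; ++j) {
      const double* dcol = dy + j * C;
      const double* ocol = out + j * C;
      double* xcol = dx + j * C;
      for (int c = 0; c < C; ++c) {
        const double g = ocol[c] > 0 ? dcol[c] : 0.0;
        xcol[c] = g * gp[c] * ip[c];
      }
    }
    return List::create(Named("dX") = dXv, Named("dgamma") = dgamma,
                        Named("dbeta") = dbeta);
  }
  const cube xhat = alias_cube(xhatv);
  const double* xhp = xhat.memptr();
  double* dgp = dgamma.memptr();
  double* dbp = dbeta.memptr();
  for (size_t j = 0; j < ncol; ++j) {
    const double* dcol = dy + j * C;
    const double* ocol = out + j * C;
    const double* xcol = xhp + j * C;
    for (int c = 0; c < C; ++c) {
      const double g = ocol[c] > 0 ? dcol[c] : 0.0;
      dgp[c] += g * xcol[c];
      dbp[c] += g;
    }
  }
  vec mean_dxhat = (gamma % dbeta) / m;
  vec mean_dxhat_xhat = (gamma % dgamma) / m;
  const double* m1 = mean_dxhat.memptr();
  const double* m2 = mean_dxhat_xhat.memptr();
  for (size_t j = 0; j < ncol; ++j) {
    const double* dcol = dy + j * C;
    const double* ocol = out + j * C;
    const double* xcol = xhp + j * C;
    double* xo = dx + j * C;
    for (int c = 0; c < C; ++c) {
      const double g = ocol[c] > 0 ? dcol[c] : 0.0;
      xo[c] = (g * gp[c] - m1[c] - xcol[c] * m2[c]) * ip[c];
    }
  }
  return List::create(Named("dX") = dXv, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// Residual tail: out = max(A + B, 0)
// [[Rcpp::export]]
NumericVector add_relu_fwd_cpp(NumericVector Av, NumericVector Bv) {
  NumericVector Yv(Rcpp::no_init(Av.size()));
  Yv.attr("dim") = Av.attr("dim");
  const double* a = Av.begin();
  const double* b = Bv.begin();
  double* y = Yv.begin();
  const R_xlen_t n = Av.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double s = a[i] + b[i];
    y[i] = s > 0 ? s : 0.0;
  }
  return Yv;
}
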