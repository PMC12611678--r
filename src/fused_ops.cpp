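#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Borrow an R matrix as an Armadillo view without copying.
static inline mat borrow(const Rcpp::NumericMatrix& m) {
  return mat(const_cast<double*>(m.begin()), m.nrow(), m.ncol(), false, true);
}
static inline vec borrow_vec(const Rcpp::NumericVector& v) {
  return vec(const_cast<double*>(v.begin()), v.size(), false, true);
}

// Fused convolution branch forward: valid stride-1 per-channel 1-D conv,
// batch normalization (per output channel f over the C*L positions), ReLU and
// global average pooling over time. Xt is the transposed input (T x C) so the
// inner convolution loop runs over contiguous memory.
//
// Row layout of the intermediate (C*L) x F tensors: r = t*C + c (t 0-based).
// [[Rcpp::export]]
Rcpp::List conv_branch_fwd_cpp(const Rcpp::NumericMatrix& Xt_,
                               const Rcpp::NumericMatrix& K_,
                               const Rcpp::NumericVector& gamma_,
                               const Rcpp::NumericVector& beta_,
                               const Rcpp::NumericVector& run_mean_,
                               const Rcpp::NumericVector& run_var_,
                               const double momentum, const double eps,
                               const bool training) {
  const mat Xt = borrow(Xt_), K = borrow(K_);
  const vec gamma = borrow_vec(gamma_), beta = borrow_vec(beta_);
  const vec run_mean = borrow_vec(run_mean_), run_var = borrow_vec(run_var_);
  const int T = Xt.n_rows, C = Xt.n_cols;
  const int k = K.n_rows, F = K.n_cols;
  const int L = T - k + 1;
  const int n = C * L;
  mat O(n, F);
  std::vector<double> tmp(L);
  for (int f = 0; f < F; ++f) {
    const double* kf = K.colptr(f);
    double* of = O.colptr(f);
    for (int c = 0; c < C; ++c) {
      const double* xc = Xt.colptr(c);
      std::fill(tmp.begin(), tmp.end(), 0.0);
      // elementwise accumulation keeps the inner loop vectorizable
      for (int u = 0; u < k; ++u) {
        const double kv = kf[u];
        const double* xp = xc + u;
        for (int t = 0; t < L; ++t) tmp[t] += kv * xp[t];
      }
      for (int t = 0; t < L; ++t) of[(size_t)t * C + c] = tmp[t];
    }
  }
  vec mu(F), va(F);
  if (training) {
    mu = mean(O, 0).t();
    va = mean(square(O), 0).t() - square(mu);
  } else {
    mu = run_mean;
    va = run_var;
  }
  vec inv_sd = 1.0 / sqrt(va + eps);
  Rcpp::NumericMatrix xhat_(n, F);
  mat xhat = borrow(xhat_);
  mat pooled(C, F, fill::zeros);
  for (int f = 0; f < F; ++f) {
    const double m0 = mu(f), is = inv_sd(f), g = gamma(f), b = beta(f);
    const double* of = O.colptr(f);
    double* xf = xhat.colptr(f);
    double* pf = pooled.colptr(f);
    for (int t = 0; t < L; ++t) {
      const size_t base = (size_t)t * C;
      for (int c = 0; c < C; ++c) {
        const double xh = (of[base + c] - m0) * is;
        xf[base + c] = xh;
        const double y = g * xh + b;
        if (y > 0) pf[c] += y;
      }
    }
    for (int c = 0; c < C; ++c) pf[c] /= L;
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("pooled") = pooled, Rcpp::Named("xhat") = xhat_,
      Rcpp::Named("inv_sd") = inv_sd);
  if (training) {
    out["run_mean"] = momentum * run_mean + (1 - momentum) * mu;
    out["run_var"] = momentum * run_var + (1 - momentum) * va;
  }
  return out;
}

// Backward of the fused branch: gradients for the kernel, BN gain/offset and
// (optionally) the input signal, given the gradient of the pooled output.
// [[Rcpp::export]]
Rcpp::List conv_branch_bwd_cpp(const Rcpp::NumericMatrix& Xt_,
                               const Rcpp::NumericMatrix& K_,
                               const Rcpp::NumericMatrix& xhat_,
                               const Rcpp::NumericVector& inv_sd_,
                               const Rcpp::NumericVector& gamma_,
                               const Rcpp::NumericVector& beta_,
                               const Rcpp::NumericMatrix& dpooled_,
                               const bool training,
                               const bool want_input_grad) {
  const mat Xt = borrow(Xt_), K = borrow(K_), xhat = borrow(xhat_);
  const mat dpooled = borrow(dpooled_);
  const vec inv_sd = borrow_vec(inv_sd_), gamma = borrow_vec(gamma_),
            beta = borrow_vec(beta_);
  const int T = Xt.n_rows, C = Xt.n_cols;
  const int k = K.n_rows, F = K.n_cols;
  const int L = T - k + 1;
  const int n = C * L;
  mat dO(n, F);
  vec ggamma(F), gbeta(F);
  for (int f = 0; f < F; ++f) {
    const double g = gamma(f), b = beta(f), is = inv_sd(f);
    const double* xf = xhat.colptr(f);
    const double* dp = dpooled.colptr(f);
    double* df = dO.colptr(f);
    double sum_dy = 0, sum_dyx = 0;
    for (int t = 0; t < L; ++t) {
      const size_t base = (size_t)t * C;
      for (int c = 0; c < C; ++c) {
        const double y = g * xf[base + c] + b;
        const double dy = (y > 0) ? dp[c] / L : 0.0;
        df[base + c] = dy;            // stash dY
        sum_dy += dy;
        sum_dyx += dy * xf[base + c];
      }
    }
    ggamma(f) = sum_dyx;
    gbeta(f) = sum_dy;
    if (training) {
      const double m1 = g * sum_dy / n, m2 = g * sum_dyx / n;
      for (int r = 0; r < n; ++r)
        df[r] = (g * df[r] - m1 - xf[r] * m2) * is;
    } else {
      for (int r = 0; r < n; ++r) df[r] = g * df[r] * is;
    }
  }
  mat gK(k, F, fill::zeros);
  for (int f = 0; f < F; ++f) {
    const double* df = dO.colptr(f);
    double* gf = gK.colptr(f);
    for (int c = 0; c < C; ++c) {
      const double* xc = Xt.colptr(c);
      for (int t = 0; t < L; ++t) {
        const double d = df[(size_t)t * C + c];
        if (d == 0.0) continue;
        const double* xp = xc + t;
        for (int u = 0; u < k; ++u) gf[u] += xp[u] * d;
      }
    }
  }
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("gK") = gK,
                                      Rcpp::Named("ggamma") = ggamma,
                                      Rcpp::Named("gbeta") = gbeta);
  if (want_input_grad) {
    mat dXt(T, C, fill::zeros);
    for (int f = 0; f < F; ++f) {
      const double* df = dO.colptr(f);
      const double* kf = K.colptr(f);
      for (int c = 0; c < C; ++c) {
        double* dc = dXt.colptr(c);
        for (int t = 0; t < L; ++t) {
          const double d = df[(size_t)t * C + c];
          if (d == 0.0) continue;
          double* dp = dc + t;
          for (int u = 0; u < k; ++u) dp[u] += d * kf[u];
        }
      }
    }
    out["dXt"] = dXt;
  }
  return out;
}

// Edge-conditioned message aggregation: S(i,:) = sum_j W_ij x_j over the
// fully connected neighborhood, with W_ij = W_ji reshaped (column-major) from
// Wflat rows over the unordered pairs (iu, ju) (1-based).
// [[Rcpp::export]]
Rcpp::NumericMatrix ecc_msg_fwd_cpp(const Rcpp::NumericMatrix& Wflat_,
                                    const Rcpp::NumericMatrix& Xh_,
                                    const Rcpp::IntegerVector& iu,
                                    const Rcpp::IntegerVector& ju) {
  const mat Wflat = borrow(Wflat_), Xh = borrow(Xh_);
  const int C = Xh.n_rows, D = Xh.n_cols;
  const int E = Wflat.n_rows;
  Rcpp::NumericMatrix S_(C, D);
  mat S = borrow(S_);
  mat W(D, D);
  vec xi(D), xj(D);
  for (int e = 0; e < E; ++e) {
    const int i = iu[e] - 1, j = ju[e] - 1;
    // rows are strided; gather the row once into a D x D kernel
    for (int d2 = 0; d2 < D; ++d2) {
      double* wc = W.colptr(d2);
      const double* src = Wflat.colptr(d2 * D) + e;
      for (int d1 = 0; d1 < D; ++d1) wc[d1] = src[(size_t)d1 * E];
    }
    xi = Xh.row(i).t();
    xj = Xh.row(j).t();
    S.row(i) += (W * xj).t();
    S.row(j) += (W * xi).t();
  }
  return S_;
}

// Backward of the message aggregation: gradients for the flattened edge
// kernels and the projected node features. dS must already carry the
// 1/(C-1) mean factor.
// [[Rcpp::export]]
Rcpp::List ecc_msg_bwd_cpp(const Rcpp::NumericMatrix& dS_,
                           const Rcpp::NumericMatrix& Wflat_,
                           const Rcpp::NumericMatrix& Xh_,
                           const Rcpp::IntegerVector& iu,
                           const Rcpp::IntegerVector& ju) {
  const mat dS = borrow(dS_), Wflat = borrow(Wflat_), Xh = borrow(Xh_);
  const int C = Xh.n_rows, D = Xh.n_cols;
  const int E = Wflat.n_rows;
  Rcpp::NumericMatrix dWflat_(E, D * D);
  mat dWflat = borrow(dWflat_);
  Rcpp::NumericMatrix dXh_(C, D);
  mat dXh = borrow(dXh_);
  mat W(D, D), dW(D, D);
  vec dmi(D), dmj(D), xi(D), xj(D);
  for (int e = 0; e < E; ++e) {
    const int i = iu[e] - 1, j = ju[e] - 1;
    for (int d2 = 0; d2 < D; ++d2) {
      double* wc = W.colptr(d2);
      const double* src = Wflat.colptr(d2 * D) + e;
      for (int d1 = 0; d1 < D; ++d1) wc[d1] = src[(size_t)d1 * E];
    }
    dmi = dS.row(i).t();
    dmj = dS.row(j).t();
    xi = Xh.row(i).t();
    xj = Xh.row(j).t();
    dW = dmi * xj.t() + dmj * xi.t();
    for (int d2 = 0; d2 < D; ++d2) {
      const double* wc = dW.colptr(d2);
      double* dst = dWflat.colptr(d2 * D) + e;
      for (int d1 = 0; d1 < D; ++d1) dst[(size_t)d1 * E] = wc[d1];
    }
    dXh.row(j) += (W.t() * dmi).t();
    dXh.row(i) += (W.t() * dmj).t();
  }
  return Rcpp::List::create(Rcpp::Named("dWflat") = dWflat_,
                            Rcpp::Named("dXh") = dXh_);
}
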