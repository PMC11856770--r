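// Element-wise and gather/scatter kernels for the network layers. Matrix
// products stay in R (BLAS); these cover the memory-bound steps: im2col
// gathers, scatter-adds, bias broadcast fused with ReLU, valid-cell average
// pooling, and GELU.

#ifndef USE_FC_LEN_T
#define USE_FC_LEN_T
#endif
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// Gather shifted copies of X (token matrix, N rows) into an im2col matrix
// (N x T*C). idx is N x T with 1-based row sources; values outside 1..N mean
// a zero (padded) cell.
// [[Rcpp::export]]
NumericMatrix cpp_gather(const NumericMatrix& X, const IntegerMatrix& idx) {
  const int N = idx.nrow(), T = idx.ncol(), C = X.ncol(), NX = X.nrow();
  NumericMatrix out = no_init(N, T * C);
  for (int t = 0; t < T; ++t) {
    const int* ix = &idx(0, t);
    for (int c = 0; c < C; ++c) {
      const double* src = &X(0, c);
      double* dst = &out(0, t * C + c);
      for (int i = 0; i < N; ++i) {
        const int s = ix[i];
        dst[i] = (s >= 1 && s <= NX) ? src[s - 1] : 0.0;
      }
    }
  }
  return out;
}

// Transpose of cpp_gather: accumulate an im2col gradient back onto the
// token grid.
// [[Rcpp::export]]
NumericMatrix cpp_scatter(const NumericMatrix& dXcol, const IntegerMatrix& idx,
                          const int C) {
  const int N = idx.nrow(), T = idx.ncol();
  NumericMatrix dX(N, C);
  for (int t = 0; t < T; ++t) {
    const int* ix = &idx(0, t);
    for (int c = 0; c < C; ++c) {
      const double* src = &dXcol(0, t * C + c);
      double* dst = &dX(0, c);
      for (int i = 0; i < N; ++i) {
        const int s = ix[i];
        if (s >= 1 && s <= N) dst[s - 1] += src[i];
      }
    }
  }
  return dX;
}

// Average pooling over the taps in idx; the divisor is the number of valid
// (in-grid) cells so constant fields stay constant at the borders.
// [[Rcpp::export]]
List cpp_pool_fwd(const NumericMatrix& X, const IntegerMatrix& idx) {
  const int N = idx.nrow(), T = idx.ncol(), C = X.ncol();
  NumericMatrix out(N, C);
  NumericVector cnt(N);
  for (int t = 0; t < T; ++t) {
    const int* ix = &idx(0, t);
    for (int i = 0; i < N; ++i)
      if (ix[i] >= 1 && ix[i] <= N) cnt[i] += 1.0;
  }
  for (int t = 0; t < T; ++t) {
    const int* ix = &idx(0, t);
    for (int c = 0; c < C; ++c) {
      const double* src = &X(0, c);
      double* dst = &out(0, c);
      for (int i = 0; i < N; ++i) {
        const int s = ix[i];
        if (s >= 1 && s <= N) dst[i] += src[s - 1];
      }
    }
  }
  for (int c = 0; c < C; ++c) {
    double* dst = &out(0, c);
    for (int i = 0; i < N; ++i) dst[i] /= cnt[i];
  }
  return List::create(Named("out") = out, Named("cnt") = cnt);
}

// [[Rcpp::export]]
NumericMatrix cpp_pool_bwd(const NumericMatrix& dout, const IntegerMatrix& idx,
                           const NumericVector& cnt) {
  const int N = idx.nrow(), T = idx.ncol(), C = dout.ncol();
  NumericMatrix dX(N, C);
  for (int t = 0; t < T; ++t) {
    const int* ix = &idx(0, t);
    for (int c = 0; c < C; ++c) {
      const double* src = &dout(0, c);
      double* dst = &dX(0, c);
      for (int i = 0; i < N; ++i) {
        const int s = ix[i];
        if (s >= 1 && s <= N) dst[s - 1] += src[i] / cnt[i];
      }
    }
  }
  return dX;
}

// M += b broadcast over rows, optionally followed by ReLU. Mutates M in
// place and returns it: callers must pass a temporary (e.g. a fresh matrix
// product), never a bound variable.
// [[Rcpp::export]]
NumericMatrix cpp_add_bias(NumericMatrix M, const NumericVector& b,
                           const bool relu) {
  const int N = M.nrow(), C = M.ncol();
  for (int c = 0; c < C; ++c) {
    const double bc = b[c];
    double* dst = &M(0, c);
    if (relu)
      for (int i = 0; i < N; ++i) {
        const double x = dst[i] + bc;
        dst[i] = x > 0.0 ? x : 0.0;
      }
    else
      for (int i = 0; i < N; ++i) dst[i] += bc;
  }
  return M;
}

// [[Rcpp::export]]
NumericMatrix cpp_relu(const NumericMatrix& X) {
  const int n = X.nrow() * X.ncol();
  NumericMatrix out(X.nrow(), X.ncol());
  const double* src = X.begin();
  double* dst = out.begin();
  for (int i = 0; i < n; ++i) dst[i] = src[i] > 0.0 ? src[i] : 0.0;
  return out;
}

// ReLU gradient using the forward output as the activity mask.
// [[Rcpp::export]]
NumericMatrix cpp_relu_bwd(const NumericMatrix& dout, const NumericMatrix& out) {
  const int n = dout.nrow() * dout.ncol();
  NumericMatrix dX = no_init(dout.nrow(), dout.ncol());
  const double* g = dout.begin();
  const double* o = out.begin();
  double* dst = dX.begin();
  for (int i = 0; i < n; ++i) dst[i] = o[i] > 0.0 ? g[i] : 0.0;
  return dX;
}

// Exact GELU: x * Phi(x) with the normal CDF.
// [[Rcpp::export]]
NumericMatrix cpp_gelu_fwd(const NumericMatrix& X) {
  const int n = X.nrow() * X.ncol();
  NumericMatrix out = no_init(X.nrow(), X.ncol());
  const double* src = X.begin();
  double* dst = out.begin();
  for (int i = 0; i < n; ++i)
    dst[i] = src[i] * 0.5 * erfc(-src[i] * M_SQRT1_2);
  return out;
}

// GELU gradient: Phi(x) + x * phi(x).
// [[Rcpp::export]]
NumericMatrix cpp_gelu_bwd(const NumericMatrix& dout, const NumericMatrix& X) {
  const int n = X.nrow() * X.ncol();
  const double inv_sqrt2pi = 0.3989422804014327;
  NumericMatrix dX = no_init(X.nrow(), X.ncol());
  const double* g = dout.begin();
  const double* x = X.begin();
  double* dst = dX.begin();
  for (int i = 0; i < n; ++i) {
    const double Phi = 0.5 * erfc(-x[i] * M_SQRT1_2);
    const double phi = inv_sqrt2pi * exp(-0.5 * x[i] * x[i]);
    dst[i] = g[i] * (Phi + x[i] * phi);
  }
  return dX;
}

// Layer normalization over each row (channel dimension), forward.
// [[Rcpp::export]]
List cpp_ln_fwd(const NumericMatrix& X, const NumericVector& gamma,
                const NumericVector& beta, const double eps) {
  const int N = X.nrow(), C = X.ncol();
  NumericMatrix xhat = no_init(N, C), out = no_init(N, C);
  NumericVector inv = no_init(N);
  std::vector<double> mu(N, 0.0), var(N, 0.0);
  for (int c = 0; c < C; ++c) {
    const double* x = &X(0, c);
    for (int i = 0; i < N; ++i) mu[i] += x[i];
  }
  for (int i = 0; i < N; ++i) mu[i] /= C;
  for (int c = 0; c < C; ++c) {
    const double* x = &X(0, c);
    for (int i = 0; i < N; ++i) {
      const double d = x[i] - mu[i];
      var[i] += d * d;
    }
  }
  for (int i = 0; i < N; ++i) inv[i] = 1.0 / std::sqrt(var[i] / C + eps);
  for (int c = 0; c < C; ++c) {
    const double* x = &X(0, c);
    double* xh = &xhat(0, c);
    double* o = &out(0, c);
    const double g = gamma[c], bb = beta[c];
    for (int i = 0; i < N; ++i) {
      const double h = (x[i] - mu[i]) * inv[i];
      xh[i] = h;
      o[i] = h * g + bb;
    }
  }
  return List::create(Named("out") = out, Named("xhat") = xhat,
                      Named("inv") = inv);
}

// Layer normalization backward:
// dX = inv * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) per row.
// [[Rcpp::export]]
List cpp_ln_bwd(const NumericMatrix& dout, const NumericMatrix& xhat,
                const NumericVector& inv, const NumericVector& gamma) {
  const int N = dout.nrow(), C = dout.ncol();
  NumericMatrix dX = no_init(N, C);
  NumericVector dgamma(C), dbeta(C);
  std::vector<double> m1(N, 0.0), m2(N, 0.0);
  for (int c = 0; c < C; ++c) {
    const double g = gamma[c];
    const double* dg = &dout(0, c);
    const double* xh = &xhat(0, c);
    double sg = 0.0, sb = 0.0;
    for (int i = 0; i < N; ++i) {
      const double dxh = dg[i] * g;
      m1[i] += dxh;
      m2[i] += dxh * xh[i];
      sg += dg[i] * xh[i];
      sb += dg[i];
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
  }
  for (int i = 0; i < N; ++i) {
    m1[i] /= C;
    m2[i] /= C;
  }
  for (int c = 0; c < C; ++c) {
    const double g = gamma[c];
    const double* dg = &dout(0, c);
    const double* xh = &xhat(0, c);
    double* dx = &dX(0, c);
    for (int i = 0; i < N; ++i)
      dx[i] = inv[i] * (dg[i] * g - m1[i] - xh[i] * m2[i]);
  }
  return List::create(Named("dX") = dX, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// Scaled dot-product attention over n independent blocks of s2 tokens.
// Q, K are (n*s2, dk); V is (n*s2, dv); all column-major with leading
// dimension N = n*s2. Per block: P = softmax(Q_b K_b' / sqrt(dk)),
// out_b = P V_b. P is returned as an (N, s2) matrix of row-wise attention
// probabilities for the backward pass.
// [[Rcpp::export]]
List cpp_attn_fwd(const NumericMatrix& Q, const NumericMatrix& K,
                  const NumericMatrix& V, const int n, const int s2) {
  int dk = Q.ncol(), dv = V.ncol(), N = Q.nrow(), m = s2;
  const double sc = 1.0 / std::sqrt((double)dk);
  const double one = 1.0, zero = 0.0;
  NumericMatrix out = no_init(N, dv);
  NumericMatrix P = no_init(N, s2);
  std::vector<double> S(s2 * s2);
  for (int b = 0; b < n; ++b) {
    const int r0 = b * s2;
    F77_CALL(dgemm)("N", "T", &m, &m, &dk, &sc, &Q(r0, 0), &N, &K(r0, 0),
                    &N, &zero, S.data(), &m FCONE FCONE);
    for (int i = 0; i < s2; ++i) {
      double mx = S[i];
      for (int j = 1; j < s2; ++j)
        if (S[i + j * s2] > mx) mx = S[i + j * s2];
      double sum = 0.0;
      for (int j = 0; j < s2; ++j) {
        const double e = exp(S[i + j * s2] - mx);
        S[i + j * s2] = e;
        sum += e;
      }
      for (int j = 0; j < s2; ++j) S[i + j * s2] /= sum;
    }
    for (int j = 0; j < s2; ++j)
      memcpy(&P(r0, j), &S[j * s2], s2 * sizeof(double));
    F77_CALL(dgemm)("N", "N", &m, &dv, &m, &one, S.data(), &m, &V(r0, 0),
                    &N, &zero, &out(r0, 0), &N FCONE FCONE);
  }
  return List::create(Named("out") = out, Named("P") = P);
}

// [[Rcpp::export]]
List cpp_attn_bwd(const NumericMatrix& dout, const NumericMatrix& P,
                  const NumericMatrix& Q, const NumericMatrix& K,
                  const NumericMatrix& V, const int n, const int s2) {
  int dk = Q.ncol(), dv = V.ncol(), N = Q.nrow(), m = s2;
  const double sc = 1.0 / std::sqrt((double)dk);
  const double one = 1.0, zero = 0.0;
  NumericMatrix dQ = no_init(N, dk), dK = no_init(N, dk);
  NumericMatrix dV = no_init(N, dv);
  std::vector<double> Pb(s2 * s2), dP(s2 * s2), dS(s2 * s2), rs(s2);
  for (int b = 0; b < n; ++b) {
    const int r0 = b * s2;
    for (int j = 0; j < s2; ++j)
      memcpy(&Pb[j * s2], &P(r0, j), s2 * sizeof(double));
    F77_CALL(dgemm)("T", "N", &m, &dv, &m, &one, Pb.data(), &m,
                    &dout(r0, 0), &N, &zero, &dV(r0, 0), &N FCONE FCONE);
    F77_CALL(dgemm)("N", "T", &m, &m, &dv, &one, &dout(r0, 0), &N,
                    &V(r0, 0), &N, &zero, dP.data(), &m FCONE FCONE);
    for (int i = 0; i < s2; ++i) {
      double acc = 0.0;
      for (int j = 0; j < s2; ++j) acc += dP[i + j * s2] * Pb[i + j * s2];
      rs[i] = acc;
    }
    for (int j = 0; j < s2; ++j)
      for (int i = 0; i < s2; ++i)
        dS[i + j * s2] = Pb[i + j * s2] * (dP[i + j * s2] - rs[i]) * sc;
    F77_CALL(dgemm)("N", "N", &m, &dk, &m, &one, dS.data(), &m, &K(r0, 0),
                    &N, &zero, &dQ(r0, 0), &N FCONE FCONE);
    F77_CALL(dgemm)("T", "N", &m, &dk, &m, &one, dS.data(), &m, &Q(r0, 0),
                    &N, &zero, &dK(r0, 0), &N FCONE FCONE);
  }
  return List::create(Named("dQ") = dQ, Named("dK") = dK, Named("dV") = dV);
}
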