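// Hot kernels of the convolutional branch.  Activations are laid out as
// channels x (positions * nodes) matrices (channel fastest), positions
// contiguous within a node.  Stride-1 'same' convolutions are computed
// tap by tap as accumulated BLAS dgemm calls on contiguous column blocks,
// so no im2col buffer is ever materialized; pooling is a grouped column
// maximum with explicit argmax for the backward pass.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
using namespace Rcpp;

// Forward convolution: Y(Cout x N) = sum_k W_k' * A(shifted by off_k) + b.
// W is (C*K) x Cout with channel fastest within tap; off gives the input
// position offset of each tap; L positions per node, n nodes.
// [[Rcpp::export(name = ".convFwd")]]
NumericMatrix convFwd(const NumericMatrix& A, const NumericMatrix& W,
                      const NumericVector& b, const IntegerVector& off,
                      int L, int n) {
  const int C = A.nrow(), CK = W.nrow(), Cout = W.ncol(), K = off.size();
  const int N = L * n;
  NumericMatrix Y(Cout, N);
  double* y = Y.begin();
  for (int j = 0; j < N; ++j)
    std::copy(b.begin(), b.end(), y + (R_xlen_t)j * Cout);
  const double one = 1.0;
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < K; ++k) {
      const int o = off[k];
      const int p0 = std::max(1, 1 - o), p1 = std::min(L, L - o);
      const int m = p1 - p0 + 1;
      if (m <= 0) continue;
      const double* a = &A(0, i * L + p0 + o - 1);
      double* yb = y + (R_xlen_t)(i * L + p0 - 1) * Cout;
      F77_CALL(dgemm)("T", "N", &Cout, &m, &C, &one, &W(k * C, 0), &CK,
                      a, &C, &one, yb, &Cout FCONE FCONE);
    }
  }
  return Y;
}

// Input gradient (transpose convolution): dX(C x N) accumulates
// W_k * dY(shifted back by off_k).
// [[Rcpp::export(name = ".convBwdInput")]]
NumericMatrix convBwdInput(const NumericMatrix& dY, const NumericMatrix& W,
                           const IntegerVector& off, int L, int n) {
  const int Cout = dY.nrow(), CK = W.nrow(), K = off.size();
  const int C = CK / K, N = L * n;
  NumericMatrix dX(C, N);
  const double one = 1.0;
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < K; ++k) {
      const int o = off[k];
      const int p0 = std::max(1, 1 - o), p1 = std::min(L, L - o);
      const int m = p1 - p0 + 1;
      if (m <= 0) continue;
      const double* dy = &dY(0, i * L + p0 - 1);
      double* dx = &dX(0, i * L + p0 + o - 1);
      F77_CALL(dgemm)("N", "N", &C, &m, &Cout, &one, &W(k * C, 0), &CK,
                      dy, &Cout, &one, dx, &C FCONE FCONE);
    }
  }
  return dX;
}

// Weight gradient: dW_k = A(shifted) * dY' per tap.
// [[Rcpp::export(name = ".convBwdWeight")]]
NumericMatrix convBwdWeight(const NumericMatrix& A, const NumericMatrix& dY,
                            const IntegerVector& off, int L, int n) {
  const int C = A.nrow(), Cout = dY.nrow(), K = off.size();
  const int CK = C * K;
  NumericMatrix dW(CK, Cout);
  const double one = 1.0;
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < K; ++k) {
      const int o = off[k];
      const int p0 = std::max(1, 1 - o), p1 = std::min(L, L - o);
      const int m = p1 - p0 + 1;
      if (m <= 0) continue;
      const double* a = &A(0, i * L + p0 + o - 1);
      const double* dy = &dY(0, i * L + p0 - 1);
      F77_CALL(dgemm)("N", "T", &C, &Cout, &m, &one, a, &C, dy, &Cout,
                      &one, &dW(k * C, 0), &CK FCONE FCONE);
    }
  }
  return dW;
}

// Column-group maximum with argmax (first maximum wins).  groups is
// P x G, 1-based column indices into A (0 = absent).
// [[Rcpp::export(name = ".groupMax")]]
List groupMax(const NumericMatrix& A, const IntegerMatrix& groups) {
  const int C = A.nrow(), G = groups.ncol(), P = groups.nrow();
  NumericMatrix out(C, G);
  IntegerMatrix arg(C, G);
  for (int g = 0; g < G; ++g) {
    const int c0 = groups(0, g) - 1;
    const double* s0 = &A(0, c0);
    for (int c = 0; c < C; ++c) {
      out(c, g) = s0[c];
      arg(c, g) = c0 + 1;
    }
    for (int p = 1; p < P; ++p) {
      const int col = groups(p, g);
      if (col <= 0) continue;
      const double* s = &A(0, col - 1);
      for (int c = 0; c < C; ++c) {
        if (s[c] > out(c, g)) {
          out(c, g) = s[c];
          arg(c, g) = col;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// Scatter the pooled gradient back onto the argmax positions.
// [[Rcpp::export(name = ".groupMaxBack")]]
NumericMatrix groupMaxBack(const NumericMatrix& dOut, const IntegerMatrix& arg,
                           int ncols) {
  const int C = dOut.nrow(), G = dOut.ncol();
  NumericMatrix dA(C, ncols);
  for (int g = 0; g < G; ++g)
    for (int c = 0; c < C; ++c)
      dA(c, arg(c, g) - 1) += dOut(c, g);
  return dA;
}

// [[Rcpp::export(name = ".leakyFwd")]]
NumericMatrix leakyFwd(const NumericMatrix& X, double slope) {
  NumericMatrix out = clone(X);
  const R_xlen_t n = out.size();
  double* p = out.begin();
  for (R_xlen_t i = 0; i < n; ++i)
    if (p[i] < 0) p[i] *= slope;
  return out;
}

// Fused dY * LeakyReLU'(pre).
// [[Rcpp::export(name = ".leakyBack")]]
NumericMatrix leakyBack(const NumericMatrix& dY, const NumericMatrix& pre,
                        double slope) {
  NumericMatrix out = clone(dY);
  const R_xlen_t n = out.size();
  double* p = out.begin();
  const double* q = pre.begin();
  for (R_xlen_t i = 0; i < n; ++i)
    if (q[i] <= 0) p[i] *= slope;
  return out;
}
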