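// Low-level primitives for the small trial-level CNN.
//
// Batch layout: a batch is a d x n matrix, one column per trial, with
// feature index c + C*y + C*H*x (channel fastest, then row, then column),
// matching R's column-major flattening of a (C, H, W) array.
// Convolution weights are F x (C*KH*KW) matrices with column index
// c + C*ky + C*KH*kx. im2col output columns are ordered
// i*OH*OW + ox*OH + oy so that the gemm result, flattened column-major,
// reproduces the same per-sample layout.

#include <Rcpp.h>
#include <cstring>

using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& X, int C, int H, int W,
                         int KH, int KW) {
  const int n = X.ncol();
  const int OH = H - KH + 1, OW = W - KW + 1;
  NumericMatrix out(C * KH * KW, n * OH * OW);
  const double* xp = &X(0, 0);
  double* op = &out(0, 0);
  const size_t xstride = X.nrow(), ostride = out.nrow();
  for (int i = 0; i < n; ++i) {
    const double* xi = xp + xstride * i;
    for (int ox = 0; ox < OW; ++ox) {
      for (int oy = 0; oy < OH; ++oy) {
        double* col = op + ostride * ((size_t)i * OH * OW + (size_t)ox * OH + oy);
        for (int kx = 0; kx < KW; ++kx) {
          std::memcpy(col + (size_t)C * KH * kx,
                      xi + C * (oy + (size_t)H * (ox + kx)),
                      sizeof(double) * C * KH);
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& cols, int C, int H, int W,
                         int KH, int KW, int n) {
  const int OH = H - KH + 1, OW = W - KW + 1;
  NumericMatrix X(C * H * W, n);
  const double* cp = &cols(0, 0);
  double* xp = &X(0, 0);
  const size_t cstride = cols.nrow(), xstride = X.nrow();
  for (int i = 0; i < n; ++i) {
    double* xi = xp + xstride * i;
    for (int ox = 0; ox < OW; ++ox) {
      for (int oy = 0; oy < OH; ++oy) {
        const double* col = cp + cstride * ((size_t)i * OH * OW + (size_t)ox * OH + oy);
        for (int kx = 0; kx < KW; ++kx) {
          double* dst = xi + C * (oy + (size_t)H * (ox + kx));
          const double* src = col + (size_t)C * KH * kx;
          for (int t = 0; t < C * KH; ++t) dst[t] += src[t];
        }
      }
    }
  }
  return X;
}

// [[Rcpp::export]]
List cpp_maxpool(const NumericMatrix& X, int C, int H, int W) {
  const int n = X.ncol();
  const int OH = H / 2, OW = W / 2;
  NumericMatrix out(C * OH * OW, n);
  IntegerMatrix arg(C * OH * OW, n);
  const double* xp = &X(0, 0);
  const size_t xstride = X.nrow();
  for (int i = 0; i < n; ++i) {
    const double* xi = xp + xstride * i;
    double* oi = &out(0, i);
    int* ai = &arg(0, i);
    for (int ox = 0; ox < OW; ++ox) {
      for (int oy = 0; oy < OH; ++oy) {
        for (int c = 0; c < C; ++c) {
          int best = 0;
          double bv = -1e300;
          for (int dx = 0; dx < 2; ++dx) {
            for (int dy = 0; dy < 2; ++dy) {
              int idx = c + C * (2 * oy + dy) + C * H * (2 * ox + dx);
              if (xi[idx] > bv) { bv = xi[idx]; best = idx; }
            }
          }
          int o = c + C * oy + C * OH * ox;
          oi[o] = bv;
          ai[o] = best;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bw(const NumericMatrix& dOut,
                             const IntegerMatrix& arg, int C, int H, int W) {
  const int n = dOut.ncol();
  NumericMatrix dX(C * H * W, n);
  for (int i = 0; i < n; ++i) {
    const double* di = &dOut(0, i);
    const int* ai = &arg(0, i);
    double* xi = &dX(0, i);
    for (int o = 0; o < dOut.nrow(); ++o) xi[ai[o]] += di[o];
  }
  return dX;
}

// ReLU returning the activated copy (mask recomputed cheaply on backward)
// [[Rcpp::export]]
NumericMatrix cpp_relu(const NumericMatrix& X) {
  NumericMatrix out(X.nrow(), X.ncol());
  const double* xp = &X(0, 0);
  double* op = &out(0, 0);
  const size_t nn = (size_t)X.nrow() * X.ncol();
  for (size_t t = 0; t < nn; ++t) op[t] = xp[t] > 0 ? xp[t] : 0;
  return out;
}

// in place: dZ[i] = 0 where Z[i] <= 0
// [[Rcpp::export]]
NumericMatrix cpp_relu_bw(NumericMatrix dZ, const NumericMatrix& Z) {
  double* dp = &dZ(0, 0);
  const double* zp = &Z(0, 0);
  const size_t nn = (size_t)dZ.nrow() * dZ.ncol();
  for (size_t t = 0; t < nn; ++t) if (zp[t] <= 0) dp[t] = 0;
  return dZ;
}

// Skinny-matrix products for the conv layers (few rows, many columns);
// hand-rolled loops vectorize well here and outrun reference BLAS.

// A (m x k) * B (k x n) + bias (m): m, k small
// [[Rcpp::export]]
NumericMatrix cpp_gemm_nn_bias(const NumericMatrix& A, const NumericMatrix& B,
                               const NumericVector& bias) {
  const int m = A.nrow(), k = A.ncol(), n = B.ncol();
  NumericMatrix C(m, n);
  const double* ap = &A(0, 0);
  const double* bp = &B(0, 0);
  const double* vp = &bias(0);
  double* cp = &C(0, 0);
  for (int j = 0; j < n; ++j) {
    double* cj = cp + (size_t)m * j;
    for (int i = 0; i < m; ++i) cj[i] = vp[i];
    const double* bj = bp + (size_t)k * j;
    for (int kk = 0; kk < k; ++kk) {
      const double b = bj[kk];
      const double* ak = ap + (size_t)m * kk;
      for (int i = 0; i < m; ++i) cj[i] += ak[i] * b;
    }
  }
  return C;
}

// A (m x n) * t(B) (k x n) -> m x k: m, k small, n large
// [[Rcpp::export]]
NumericMatrix cpp_gemm_nt(const NumericMatrix& A, const NumericMatrix& B) {
  const int m = A.nrow(), n = A.ncol(), k = B.nrow();
  NumericMatrix C(m, k);
  const double* ap = &A(0, 0);
  const double* bp = &B(0, 0);
  double* cp = &C(0, 0);
  for (int j = 0; j < n; ++j) {
    const double* aj = ap + (size_t)m * j;
    const double* bj = bp + (size_t)k * j;
    for (int kk = 0; kk < k; ++kk) {
      const double b = bj[kk];
      double* ck = cp + (size_t)m * kk;
      for (int i = 0; i < m; ++i) ck[i] += aj[i] * b;
    }
  }
  return C;
}

// t(A) (m x k) * B (m x n) -> k x n: m, k small, n large
// [[Rcpp::export]]
NumericMatrix cpp_gemm_tn(const NumericMatrix& A, const NumericMatrix& B) {
  const int m = A.nrow(), k = A.ncol(), n = B.ncol();
  NumericMatrix C(k, n);
  const double* ap = &A(0, 0);
  const double* bp = &B(0, 0);
  double* cp = &C(0, 0);
  for (int j = 0; j < n; ++j) {
    const double* bj = bp + (size_t)m * j;
    double* cj = cp + (size_t)k * j;
    for (int i = 0; i < m; ++i) {
      const double b = bj[i];
      const double* ai = ap + i;  // stride m over kk
      for (int kk = 0; kk < k; ++kk) cj[kk] += ai[(size_t)m * kk] * b;
    }
  }
  return C;
}

// row sums of a wide matrix
// [[Rcpp::export]]
NumericVector cpp_row_sums(const NumericMatrix& A) {
  const int m = A.nrow(), n = A.ncol();
  NumericVector out(m);
  const double* ap = &A(0, 0);
  double* op = &out(0);
  for (int j = 0; j < n; ++j) {
    const double* aj = ap + (size_t)m * j;
    for (int i = 0; i < m; ++i) op[i] += aj[i];
  }
  return out;
}

// gather per-sample column blocks (P contiguous columns per sample)
// [[Rcpp::export]]
NumericMatrix cpp_slice_cols(const NumericMatrix& cols,
                             const IntegerVector& idx, int P) {
  const int m = cols.nrow(), k = idx.size();
  NumericMatrix out(m, (size_t)k * P);
  const double* cp = &cols(0, 0);
  double* op = &out(0, 0);
  for (int t = 0; t < k; ++t) {
    std::memcpy(op + (size_t)m * P * t,
                cp + (size_t)m * P * (idx[t] - 1),
                sizeof(double) * (size_t)m * P);
  }
  return out;
}
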