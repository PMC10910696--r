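// Hot numerical kernels for the attention blocks: row softmax (forward and
// backward) and deterministic top-k row selection with lowest-index tie
// breaking. Everything else runs through BLAS-backed R operations.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// max over groups of K consecutive columns (C x P*K -> C x P) with the
// argmax recorded for the backward pass; ties keep the first member
// [[Rcpp::export]]
List cpp_group_max(const NumericMatrix& v, const int K) {
  const int C = v.nrow(), PK = v.ncol();
  const int P = PK / K;
  NumericMatrix best(C, P);
  IntegerMatrix arg(C, P);
  const double* vp = v.begin();
  for (int p = 0; p < P; ++p) {
    const double* blk = vp + (size_t)p * K * C;
    double* bp = best.begin() + (size_t)p * C;
    int* ap = arg.begin() + (size_t)p * C;
    for (int c = 0; c < C; ++c) { bp[c] = blk[c]; ap[c] = 1; }
    for (int k = 1; k < K; ++k) {
      const double* col = blk + (size_t)k * C;
      for (int c = 0; c < C; ++c)
        if (col[c] > bp[c]) { bp[c] = col[c]; ap[c] = k + 1; }
    }
  }
  return List::create(_["max"] = best, _["argk"] = arg);
}

// route the gradient to each group's argmax member
// [[Rcpp::export]]
NumericMatrix cpp_group_max_bwd(const NumericMatrix& g,
                                const IntegerMatrix& arg, const int K) {
  const int C = g.nrow(), P = g.ncol();
  NumericMatrix out(C, P * K);
  for (int p = 0; p < P; ++p)
    for (int c = 0; c < C; ++c) {
      int k = arg(c, p) - 1;
      out(c, p * K + k) = g(c, p);
    }
  return out;
}

// gather kernel patches into columns: x is Cin x Pin, idx is k2 x Pout with
// 1-based input positions (0 marks zero padding)
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& x, const IntegerMatrix& idx) {
  const int Cin = x.nrow(), k2 = idx.nrow(), P = idx.ncol();
  NumericMatrix cols(Cin * k2, P);
  const double* xp = x.begin();
  double* cp = cols.begin();
  for (int p = 0; p < P; ++p)
    for (int j = 0; j < k2; ++j) {
      int id = idx(j, p);
      if (id > 0) {
        const double* src = xp + (size_t)(id - 1) * Cin;
        double* dst = cp + (size_t)p * (Cin * k2) + (size_t)j * Cin;
        std::copy(src, src + Cin, dst);
      }
    }
  return cols;
}

// scatter-add the im2col gradient back onto the input map
// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& dcols, const IntegerMatrix& idx,
                         const int Pin) {
  const int k2 = idx.nrow(), P = idx.ncol();
  const int Cin = dcols.nrow() / k2;
  NumericMatrix dX(Cin, Pin);
  const double* gp = dcols.begin();
  double* dp = dX.begin();
  for (int p = 0; p < P; ++p)
    for (int j = 0; j < k2; ++j) {
      int id = idx(j, p);
      if (id > 0) {
        const double* src = gp + (size_t)p * (Cin * k2) + (size_t)j * Cin;
        double* dst = dp + (size_t)(id - 1) * Cin;
        for (int c = 0; c < Cin; ++c) dst[c] += src[c];
      }
    }
  return dX;
}

// per-row top-k indices (1-based), decreasing value, ties toward the lower
// index for determinism across platforms. Rows are scanned through an
// insertion buffer; for the symmetric similarity matrices this is used on,
// cpp_topk_sym reads columns instead for contiguous access.
static void topk_scan(const double* row, const int stride, const int p,
                      const int k, int* out) {
  std::vector<double> bv(k);
  std::vector<int> bi(k);
  int filled = 0;
  for (int j = 0; j < p; ++j) {
    double v = row[(size_t)j * stride];
    if (filled == k && v <= bv[k - 1]) continue;
    int pos = (filled < k) ? filled : k - 1;
    // insert keeping decreasing order; strict > keeps earlier (lower) index
    while (pos > 0 && v > bv[pos - 1]) {
      bv[pos] = bv[pos - 1];
      bi[pos] = bi[pos - 1];
      --pos;
    }
    bv[pos] = v;
    bi[pos] = j;
    if (filled < k) ++filled;
  }
  for (int j = 0; j < k; ++j) out[j] = bi[j] + 1;
}

// [[Rcpp::export]]
IntegerMatrix cpp_topk_rows(const NumericMatrix& S, const int k) {
  const int n = S.nrow(), p = S.ncol();
  IntegerMatrix idx(n, k);
  std::vector<int> buf(k);
  for (int i = 0; i < n; ++i) {
    topk_scan(&S(i, 0), n, p, k, buf.data());
    for (int j = 0; j < k; ++j) idx(i, j) = buf[j];
  }
  return idx;
}

// top-k for symmetric S: row i equals column i, which is contiguous
// [[Rcpp::export]]
IntegerMatrix cpp_topk_sym(const NumericMatrix& S, const int k) {
  const int p = S.ncol();
  IntegerMatrix idx(p, k);
  std::vector<int> buf(k);
  for (int i = 0; i < p; ++i) {
    topk_scan(&S(0, i), 1, p, k, buf.data());
    for (int j = 0; j < k; ++j) idx(i, j) = buf[j];
  }
  return idx;
}
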