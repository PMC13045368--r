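#include <Rcpp.h>
using namespace Rcpp;

// Gather the 3x3 neighborhoods of every output pixel into an im2col
// matrix. X is (P x C); idx is (P x 9) of 1-based row indices where any
// index > P denotes the zero-padding sentinel. Returns (P x 9C) with
// column blocks ordered by neighbor offset j, then channel c.
// [[Rcpp::export(name = ".im2col_gather")]]
NumericMatrix im2col_gather(NumericMatrix X, IntegerMatrix idx) {
  const int P = X.nrow(), C = X.ncol(), n = idx.nrow();
  NumericMatrix out(n, 9 * C);
  for (int j = 0; j < 9; ++j) {
    const int* id = &idx(0, j);
    for (int c = 0; c < C; ++c) {
      const double* xc = &X(0, c);
      double* oc = &out(0, j * C + c);
      for (int i = 0; i < n; ++i) {
        const int t = id[i];
        oc[i] = (t <= P) ? xc[t - 1] : 0.0;
      }
    }
  }
  return out;
}

// Scatter-add the transpose operation of im2col_gather: dcols is
// (P x 9C), idx as above; accumulates into a (P x C) gradient.
// [[Rcpp::export(name = ".col2im_scatter")]]
NumericMatrix col2im_scatter(NumericMatrix dcols, IntegerMatrix idx, int C) {
  const int n = dcols.nrow();
  const int P = n;  // output pixels == input pixels for stride-1 same conv
  NumericMatrix out(P, C);
  for (int j = 0; j < 9; ++j) {
    const int* id = &idx(0, j);
    for (int c = 0; c < C; ++c) {
      const double* dc = &dcols(0, j * C + c);
      double* oc = &out(0, c);
      for (int i = 0; i < n; ++i) {
        const int t = id[i];
        if (t <= P) oc[t - 1] += dc[i];
      }
    }
  }
  return out;
}

// SiLU activation x * sigmoid(x), elementwise.
// [[Rcpp::export(name = ".silu_cpp")]]
NumericMatrix silu_cpp(NumericMatrix x) {
  const R_xlen_t n = x.size();
  NumericMatrix out(x.nrow(), x.ncol());
  const double* xi = x.begin(); double* oi = out.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double s = 1.0 / (1.0 + std::exp(-xi[i]));
    oi[i] = xi[i] * s;
  }
  return out;
}

// Derivative of SiLU: s(x) * (1 + x * (1 - s(x))).
// [[Rcpp::export(name = ".silu_grad_cpp")]]
NumericMatrix silu_grad_cpp(NumericMatrix x) {
  const R_xlen_t n = x.size();
  NumericMatrix out(x.nrow(), x.ncol());
  const double* xi = x.begin(); double* oi = out.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double s = 1.0 / (1.0 + std::exp(-xi[i]));
    oi[i] = s * (1.0 + xi[i] * (1.0 - s));
  }
  return out;
}

// Segment-table variants: seg is an (m x 4) integer matrix with columns
// (j0, dst0, src0, len) describing maximal runs where the gather index
// increments by one; src0 == 0 marks a zero-padding run. All 0-based
// except src0/dst0 which are 1-based (R convention).
// [[Rcpp::export(name = ".im2col_gather_seg")]]
NumericMatrix im2col_gather_seg(NumericMatrix X, IntegerMatrix seg, int n) {
  const int C = X.ncol(), P = X.nrow(), m = seg.nrow();
  NumericMatrix out(n, 9 * C);
  double* ob = out.begin();
  const double* xb = X.begin();
  for (int s = 0; s < m; ++s) {
    const int j = seg(s, 0), dst = seg(s, 1) - 1, src = seg(s, 2), len = seg(s, 3);
    if (src == 0) continue;  // freshly allocated matrix is already zero
    for (int c = 0; c < C; ++c)
      std::memcpy(ob + (size_t)(j * C + c) * n + dst,
                  xb + (size_t)c * P + (src - 1), len * sizeof(double));
  }
  return out;
}

// [[Rcpp::export(name = ".col2im_scatter_seg")]]
NumericMatrix col2im_scatter_seg(NumericMatrix dcols, IntegerMatrix seg,
                                 int P, int C) {
  const int n = dcols.nrow(), m = seg.nrow();
  NumericMatrix out(P, C);
  double* ob = out.begin();
  const double* db = dcols.begin();
  for (int s = 0; s < m; ++s) {
    const int j = seg(s, 0), dst = seg(s, 1) - 1, src = seg(s, 2), len = seg(s, 3);
    if (src == 0) continue;
    for (int c = 0; c < C; ++c) {
      double* oc = ob + (size_t)c * P + (src - 1);
      const double* dc = db + (size_t)(j * C + c) * n + dst;
      for (int i = 0; i < len; ++i) oc[i] += dc[i];
    }
  }
  return out;
}

// In-place row-vector (bias) addition: Y[i, c] += b[c]. Only safe on a
// freshly allocated matrix with no other references.
// [[Rcpp::export(name = ".add_rowvec_inplace")]]
NumericMatrix add_rowvec_inplace(NumericMatrix Y, NumericVector b) {
  const int n = Y.nrow(), C = Y.ncol();
  double* yb = Y.begin();
  for (int c = 0; c < C; ++c) {
    const double bc = b[c];
    double* yc = yb + (size_t)c * n;
    for (int i = 0; i < n; ++i) yc[i] += bc;
  }
  return Y;
}
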