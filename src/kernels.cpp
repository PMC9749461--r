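#include <Rcpp.h>
using namespace Rcpp;

// Row-wise unbiased sample variance with pairwise NA removal.
// Rows with fewer than two observed values get NA.
// [[Rcpp::export]]
NumericVector row_vars_cpp(const NumericMatrix& x) {
  const R_xlen_t nr = x.nrow(), nc = x.ncol();
  NumericVector out(nr);
  const double* px = &x[0];
  std::vector<double> sum(nr, 0.0), ss(nr, 0.0), mu(nr, 0.0);
  std::vector<int> cnt(nr, 0);
  for (R_xlen_t j = 0; j < nc; ++j) {
    const double* col = px + j * nr;
    for (R_xlen_t i = 0; i < nr; ++i) {
      const double v = col[i];
      if (!ISNAN(v)) { sum[i] += v; ++cnt[i]; }
    }
  }
  for (R_xlen_t i = 0; i < nr; ++i) mu[i] = cnt[i] > 0 ? sum[i] / cnt[i] : 0.0;
  for (R_xlen_t j = 0; j < nc; ++j) {
    const double* col = px + j * nr;
    for (R_xlen_t i = 0; i < nr; ++i) {
      const double v = col[i];
      if (!ISNAN(v)) { const double d = v - mu[i]; ss[i] += d * d; }
    }
  }
  for (R_xlen_t i = 0; i < nr; ++i) {
    out[i] = cnt[i] < 2 ? NA_REAL : ss[i] / (cnt[i] - 1);
  }
  return out;
}

// Two-sample KS statistics of one sorted sample against many candidate
// samples stored as presorted columns of `ysort` (padded beyond `yn[j]`).
// `cols` holds 0-based column indices to evaluate. Classic merge walk,
// advancing through ties in both samples before updating the gap.
// [[Rcpp::export]]
NumericVector ks_stat_sorted_cpp(const NumericVector& xsort,
                                 const NumericMatrix& ysort,
                                 const IntegerVector& yn,
                                 const IntegerVector& cols) {
  const int n = xsort.size();
  const int nr = ysort.nrow();
  const double* px = &xsort[0];
  const double* pys = &ysort[0];
  NumericVector out(cols.size());
  for (int c = 0; c < cols.size(); ++c) {
    const int col = cols[c];
    const double* py = pys + (R_xlen_t)col * nr;
    const int m = yn[col];
    int i = 0, j = 0;
    double fx = 0.0, fy = 0.0, d = 0.0;
    while (i < n && j < m) {
      const double xv = px[i], yv = py[j];
      if (xv <= yv) {
        do { ++i; } while (i < n && px[i] == xv);
        fx = (double)i / n;
      }
      if (yv <= xv) {
        do { ++j; } while (j < m && py[j] == yv);
        fy = (double)j / m;
      }
      const double gap = std::fabs(fx - fy);
      if (gap > d) d = gap;
    }
    // remaining tail: the exhausted sample's ecdf is 1, the other keeps
    // climbing from its current value, so the widest tail gap is 1 - f.
    if (i < n || j < m) {
      const double tail = 1.0 - (i < n ? fx : fy);
      if (tail > d) d = tail;
    }
    out[c] = d;
  }
  return out;
}

// Base-2 inverse logit: 2^m / (1 + 2^m), single pass.
// [[Rcpp::export]]
NumericMatrix inv_logit2_cpp(const NumericMatrix& m) {
  const R_xlen_t n = m.size();
  NumericMatrix out(m.nrow(), m.ncol());
  const double* pin = &m[0];
  double* pout = &out[0];
  const double ln2 = 0.6931471805599453;
  for (R_xlen_t i = 0; i < n; ++i) {
    pout[i] = 1.0 / (1.0 + std::exp(-pin[i] * ln2));
  }
  return out;
}
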