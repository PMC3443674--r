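// Bootstrap evaluation of the subset statistics. The resample index
// matrices are drawn in R (one column per bootstrap replicate, 1-based
// sample indices within each group) so that all randomness flows through
// R's RNG; this file only evaluates the statistics on each resample.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static std::vector<arma::uvec> convert_subsets(const List& subsets) {
  std::vector<arma::uvec> out(subsets.size());
  for (R_xlen_t s = 0; s < subsets.size(); ++s) {
    IntegerVector v = subsets[s];
    arma::uvec u(v.size());
    for (R_xlen_t i = 0; i < v.size(); ++i) u[i] = v[i] - 1;
    out[s] = u;
  }
  return out;
}

static arma::uvec col_idx(const IntegerMatrix& idx, int b) {
  arma::uvec u(idx.nrow());
  for (int i = 0; i < idx.nrow(); ++i) u[i] = idx(i, b) - 1;
  return u;
}

// Per-gene mean and variance (denominator n-1) of the columns of x listed
// in one index-matrix column, accumulated in a single cache-friendly sweep
// over the selected columns.
static void resample_moments(const arma::mat& x, const IntegerMatrix& idx,
                             int b, arma::vec& m, arma::vec& v) {
  const arma::uword G = x.n_rows;
  const int n = idx.nrow();
  m.zeros(G);
  v.zeros(G);
  for (int j = 0; j < n; ++j) {
    const double* c = x.colptr(idx(j, b) - 1);
    for (arma::uword g = 0; g < G; ++g) {
      m[g] += c[g];
      v[g] += c[g] * c[g];
    }
  }
  m /= n;
  v = (v - n * arma::square(m)) / (n - 1);
}

// [[Rcpp::export]]
NumericMatrix cpp_boot_diag(const arma::mat& x1, const arma::mat& x2,
                            const List& subsets,
                            const IntegerMatrix& idx1,
                            const IntegerMatrix& idx2,
                            double var_floor) {
  const int B = idx1.ncol();
  const double n1 = idx1.nrow(), n2 = idx2.nrow();
  std::vector<arma::uvec> sub = convert_subsets(subsets);
  NumericMatrix out(sub.size(), B);
  arma::vec m1, v1, m2, v2;
  for (int b = 0; b < B; ++b) {
    resample_moments(x1, idx1, b, m1, v1);
    resample_moments(x2, idx2, b, m2, v2);
    v1 = arma::clamp(v1, var_floor, arma::datum::inf);
    v2 = arma::clamp(v2, var_floor, arma::datum::inf);
    arma::vec t2 = arma::square(m1 - m2) / (v1 / n1 + v2 / n2);
    for (size_t s = 0; s < sub.size(); ++s)
      out(s, b) = arma::accu(t2.elem(sub[s]));
  }
  return out;
}

// Subset-major evaluation: each subset's gene block is copied into a
// contiguous p x n matrix once, and per replicate the resampled columns are
// gathered from it; S_i = (A A' - n m m')/(n - 1) avoids re-centring.
// [[Rcpp::export]]
NumericMatrix cpp_boot_full(const arma::mat& x1, const arma::mat& x2,
                            const List& subsets,
                            const IntegerMatrix& idx1,
                            const IntegerMatrix& idx2) {
  const int B = idx1.ncol();
  const double n1 = idx1.nrow(), n2 = idx2.nrow();
  std::vector<arma::uvec> sub = convert_subsets(subsets);
  std::vector<arma::uvec> cols1(B), cols2(B);
  for (int b = 0; b < B; ++b) {
    cols1[b] = col_idx(idx1, b);
    cols2[b] = col_idx(idx2, b);
  }
  NumericMatrix out(sub.size(), B);
  for (size_t s = 0; s < sub.size(); ++s) {
    arma::mat x1s = x1.rows(sub[s]);
    arma::mat x2s = x2.rows(sub[s]);
    for (int b = 0; b < B; ++b) {
      arma::mat a1 = x1s.cols(cols1[b]);
      arma::mat a2 = x2s.cols(cols2[b]);
      arma::vec m1 = arma::mean(a1, 1), m2 = arma::mean(a2, 1);
      arma::mat w =
        (a1 * a1.t() - n1 * m1 * m1.t()) / ((n1 - 1) * n1) +
        (a2 * a2.t() - n2 * m2 * m2.t()) / ((n2 - 1) * n2);
      arma::vec d = m1 - m2;
      arma::vec sol;
      if (!arma::solve(sol, w, d,
                       arma::solve_opts::likely_sympd +
                         arma::solve_opts::no_approx))
        stop("singular combined covariance matrix in bootstrap replicate %d",
             b + 1);
      out(s, b) = arma::dot(d, sol);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_boot_paired(const arma::mat& d0, const List& subsets,
                              const IntegerMatrix& idx, double var_floor) {
  const int B = idx.ncol();
  const double n = d0.n_cols;
  std::vector<arma::uvec> sub = convert_subsets(subsets);
  NumericMatrix out(sub.size(), B);
  arma::vec dbar, v;
  for (int b = 0; b < B; ++b) {
    resample_moments(d0, idx, b, dbar, v);
    v = arma::clamp(v, var_floor, arma::datum::inf);
    arma::vec t2 = n * arma::square(dbar) / v;
    for (size_t s = 0; s < sub.size(); ++s)
      out(s, b) = arma::accu(t2.elem(sub[s]));
  }
  return out;
}
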