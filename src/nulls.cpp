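// Structured-shuffle null distributions of the cross-maze profile
// correlation. Each repetition shuffles both mazes' trials-by-epochs
// matrices within the factor's strata, rebuilds the 72-element trial-type
// profiles and recomputes the Pearson correlation. All randomness comes
// from R's RNG stream so results are reproducible via set.seed().
#include <Rcpp.h>
using namespace Rcpp;

namespace {

// Fisher-Yates permutation of v[0..n-1] using R's RNG.
inline void permute(double* v, int n) {
  for (int j = n - 1; j > 0; --j) {
    int k = (int)(unif_rand() * (j + 1));
    if (k > j) k = j;
    std::swap(v[j], v[k]);
  }
}

// Mean profile (type-major, epoch-minor) of an n x 9 matrix.
void profile_of(const std::vector<double>& m, const IntegerVector& type,
                const std::vector<double>& inv_count, int n, int ne,
                std::vector<double>& prof) {
  std::fill(prof.begin(), prof.end(), 0.0);
  for (int i = 0; i < n; ++i) {
    int t = type[i] - 1;
    for (int e = 0; e < ne; ++e) prof[t * ne + e] += m[i * ne + e];
  }
  for (size_t t = 0; t < inv_count.size(); ++t)
    for (int e = 0; e < ne; ++e) prof[t * ne + e] *= inv_count[t];
}

double pearson(const std::vector<double>& x, const std::vector<double>& y) {
  int n = x.size();
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  double sxy = 0, sxx = 0, syy = 0;
  for (int i = 0; i < n; ++i) {
    double dx = x[i] - mx, dy = y[i] - my;
    sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
  }
  if (sxx <= 0 || syy <= 0) return NA_REAL;
  return sxy / std::sqrt(sxx * syy);
}

// Copy an R matrix into a row-major buffer.
void to_rowmajor(const NumericMatrix& m, std::vector<double>& out) {
  int n = m.nrow(), ne = m.ncol();
  out.resize((size_t)n * ne);
  for (int i = 0; i < n; ++i)
    for (int e = 0; e < ne; ++e) out[i * ne + e] = m(i, e);
}

std::vector<double> inv_counts(const IntegerVector& type) {
  int mx = 0;
  for (int i = 0; i < type.size(); ++i) if (type[i] > mx) mx = type[i];
  std::vector<double> cnt(mx, 0.0);
  for (int i = 0; i < type.size(); ++i) cnt[type[i] - 1] += 1.0;
  for (int t = 0; t < mx; ++t) cnt[t] = 1.0 / cnt[t];
  return cnt;
}

} // namespace

// [[Rcpp::export]]
NumericVector null_r_epoch(NumericMatrix m1, NumericMatrix m2,
                           IntegerVector type1, IntegerVector type2,
                           int n_shuffles) {
  int n1 = m1.nrow(), n2 = m2.nrow(), ne = m1.ncol();
  std::vector<double> b1, b2, s1, s2, p1(8 * ne), p2(8 * ne);
  to_rowmajor(m1, b1); to_rowmajor(m2, b2);
  std::vector<double> ic1 = inv_counts(type1), ic2 = inv_counts(type2);
  p1.resize(ic1.size() * ne); p2.resize(ic2.size() * ne);
  NumericVector out(n_shuffles);
  RNGScope scope;
  for (int rep = 0; rep < n_shuffles; ++rep) {
    s1 = b1; s2 = b2;
    for (int i = 0; i < n1; ++i) permute(&s1[i * ne], ne);
    for (int i = 0; i < n2; ++i) permute(&s2[i * ne], ne);
    profile_of(s1, type1, ic1, n1, ne, p1);
    profile_of(s2, type2, ic2, n2, ne, p2);
    out[rep] = pearson(p1, p2);
  }
  return out;
}

// pairs: k x 2 matrix of 0-based row indices (nonrewarded, rewarded mate);
// each matched cell pair is swapped with probability 1/2, per epoch.
// [[Rcpp::export]]
NumericVector null_r_reward(NumericMatrix m1, NumericMatrix m2,
                            IntegerVector type1, IntegerVector type2,
                            IntegerMatrix pairs1, IntegerMatrix pairs2,
                            int n_shuffles) {
  int n1 = m1.nrow(), n2 = m2.nrow(), ne = m1.ncol();
  std::vector<double> b1, b2, s1, s2;
  to_rowmajor(m1, b1); to_rowmajor(m2, b2);
  std::vector<double> ic1 = inv_counts(type1), ic2 = inv_counts(type2);
  std::vector<double> p1(ic1.size() * ne), p2(ic2.size() * ne);
  NumericVector out(n_shuffles);
  RNGScope scope;
  for (int rep = 0; rep < n_shuffles; ++rep) {
    s1 = b1; s2 = b2;
    for (int q = 0; q < pairs1.nrow(); ++q) {
      int lo = pairs1(q, 0), hi = pairs1(q, 1);
      for (int e = 0; e < ne; ++e)
        if (unif_rand() < 0.5) std::swap(s1[lo * ne + e], s1[hi * ne + e]);
    }
    for (int q = 0; q < pairs2.nrow(); ++q) {
      int lo = pairs2(q, 0), hi = pairs2(q, 1);
      for (int e = 0; e < ne; ++e)
        if (unif_rand() < 0.5) std::swap(s2[lo * ne + e], s2[hi * ne + e]);
    }
    profile_of(s1, type1, ic1, n1, ne, p1);
    profile_of(s2, type2, ic2, n2, ne, p2);
    out[rep] = pearson(p1, p2);
  }
  return out;
}

namespace {
// Permute column e of the row-major buffer across the given rows.
void permute_rows_col(std::vector<double>& m, const IntegerVector& rows,
                      int e, int ne, std::vector<double>& scratch) {
  int k = rows.size();
  scratch.resize(k);
  for (int i = 0; i < k; ++i) scratch[i] = m[rows[i] * ne + e];
  permute(scratch.data(), k);
  for (int i = 0; i < k; ++i) m[rows[i] * ne + e] = scratch[i];
}
}

// rew*/non*: 0-based row indices of the rewarded / nonrewarded strata.
// [[Rcpp::export]]
NumericVector null_r_position(NumericMatrix m1, NumericMatrix m2,
                              IntegerVector type1, IntegerVector type2,
                              IntegerVector rew1, IntegerVector non1,
                              IntegerVector rew2, IntegerVector non2,
                              int n_shuffles) {
  int n1 = m1.nrow(), n2 = m2.nrow(), ne = m1.ncol();
  std::vector<double> b1, b2, s1, s2, scratch;
  to_rowmajor(m1, b1); to_rowmajor(m2, b2);
  std::vector<double> ic1 = inv_counts(type1), ic2 = inv_counts(type2);
  std::vector<double> p1(ic1.size() * ne), p2(ic2.size() * ne);
  NumericVector out(n_shuffles);
  RNGScope scope;
  for (int rep = 0; rep < n_shuffles; ++rep) {
    s1 = b1; s2 = b2;
    for (int e = 0; e < ne; ++e) {
      permute_rows_col(s1, rew1, e, ne, scratch);
      permute_rows_col(s1, non1, e, ne, scratch);
      permute_rows_col(s2, rew2, e, ne, scratch);
      permute_rows_col(s2, non2, e, ne, scratch);
    }
    profile_of(s1, type1, ic1, n1, ne, p1);
    profile_of(s2, type2, ic2, n2, ne, p2);
    out[rep] = pearson(p1, p2);
  }
  return out;
}
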