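#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Quality of a descending stable ranking of `scores`, partitioned into
// consecutive clusters of `cluster_size`: Pearson moment skewness of the
// per-cluster positive percentages times the first-cluster percentage.
// Mirrors cluster_distribution() + asymmetry_index() + quality_score() in R;
// ties are broken by input order (stable sort), matching order(method="radix").
static double quality_from_order(const std::vector<int>& ord,
                                 const IntegerVector& labels,
                                 int cluster_size) {
  const int n = ord.size();
  const int k = (n + cluster_size - 1) / cluster_size;
  if (k < 2) return NA_REAL;
  std::vector<double> counts(k, 0.0), sizes(k, 0.0);
  for (int i = 0; i < n; ++i) {
    const int c = i / cluster_size;
    sizes[c] += 1.0;
    if (labels[ord[i]] == 1) counts[c] += 1.0;
  }
  std::vector<double> pct(k);
  for (int c = 0; c < k; ++c) pct[c] = 100.0 * counts[c] / sizes[c];
  double mu = 0.0;
  for (int c = 0; c < k; ++c) mu += pct[c];
  mu /= k;
  double m2 = 0.0, m3 = 0.0;
  for (int c = 0; c < k; ++c) {
    const double d = pct[c] - mu;
    m2 += d * d;
    m3 += d * d * d;
  }
  m2 /= k;
  m3 /= k;
  if (m2 == 0.0) return 0.0;
  return (m3 / std::pow(m2, 1.5)) * pct[0];
}

static std::vector<int> stable_desc_order(const std::vector<double>& s) {
  std::vector<int> ord(s.size());
  std::iota(ord.begin(), ord.end(), 0);
  std::stable_sort(ord.begin(), ord.end(),
                   [&s](int a, int b) { return s[a] > s[b]; });
  return ord;
}

// [[Rcpp::export(name = ".quality_from_scores_cpp")]]
double quality_from_scores_cpp(NumericVector scores, IntegerVector labels,
                               int cluster_size) {
  const int n = scores.size();
  std::vector<double> s(scores.begin(), scores.end());
  std::vector<int> ord = stable_desc_order(s);
  double q = quality_from_order(ord, labels, cluster_size);
  (void)n;
  return q;
}

// Objective used by the coefficient optimizer: score = X %*% coef, then
// ranking quality. Kept in C++ because the pattern search evaluates it
// thousands of times per descriptor combination.
// [[Rcpp::export(name = ".quality_objective_cpp")]]
double quality_objective_cpp(NumericMatrix X, NumericVector coef,
                             IntegerVector labels, int cluster_size) {
  const int n = X.nrow(), k = X.ncol();
  if (coef.size() != k) stop("coefficient length does not match X");
  std::vector<double> s(n, 0.0);
  for (int j = 0; j < k; ++j) {
    const double c = coef[j];
    if (c == 0.0) continue;
    const double* col = &X(0, j);
    for (int i = 0; i < n; ++i) s[i] += c * col[i];
  }
  std::vector<int> ord = stable_desc_order(s);
  return quality_from_order(ord, labels, cluster_size);
}
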