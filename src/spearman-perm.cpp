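#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Exact two-sided permutation p-value for the Spearman correlation of two
// rank vectors (midranks allowed). Enumerates all n! pairings; because the
// rank marginals are fixed under permutation, |rho| ordering is equivalent
// to |S - c| ordering with S = sum(rx * ry_perm) and c = n * mean(rx) *
// mean(ry), so only the cross-product sum is evaluated per permutation.
// Feasible up to n = 10 (3.6e6 permutations).

// [[Rcpp::export]]
double spearman_perm_pvalue(Rcpp::NumericVector rx, Rcpp::NumericVector ry) {
  const int n = rx.size();
  if (n != ry.size()) Rcpp::stop("rank vectors must have equal length");
  if (n < 2 || n > 10) Rcpp::stop("exact enumeration supports 2 <= n <= 10");

  double mx = 0.0, my = 0.0;
  for (int i = 0; i < n; ++i) { mx += rx[i]; my += ry[i]; }
  mx /= n; my /= n;
  const double c = n * mx * my;

  double s_obs = 0.0;
  for (int i = 0; i < n; ++i) s_obs += rx[i] * ry[i];
  const double target = std::fabs(s_obs - c) - 1e-9;

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  long long count = 0, total = 0;
  do {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += rx[i] * ry[idx[i]];
    if (std::fabs(s - c) >= target) ++count;
    ++total;
  } while (std::next_permutation(idx.begin(), idx.end()));

  return static_cast<double>(count) / static_cast<double>(total);
}
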