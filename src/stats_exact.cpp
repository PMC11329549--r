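// Exact permutation null distribution of the Spearman statistic
// S = sum(d^2) for small n (no ties), by full enumeration.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Counts of each achievable S = sum((rank_x - perm)^2) over all n!
// permutations. Index i of the result corresponds to S = i.
// [[Rcpp::export]]
NumericVector cpp_spearman_s_null(int n) {
  if (n < 2 || n > 10) stop("exact Spearman enumeration supports 2 <= n <= 10");
  int smax = n * (n * n - 1) / 3;
  std::vector<double> cnt(smax + 1, 0.0);
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i + 1;
  do {
    int s = 0;
    for (int i = 0; i < n; ++i) {
      int d = (i + 1) - perm[i];
      s += d * d;
    }
    cnt[s] += 1.0;
  } while (std::next_permutation(perm.begin(), perm.end()));
  return NumericVector(cnt.begin(), cnt.end());
}
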