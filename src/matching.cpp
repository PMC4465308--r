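#include <Rcpp.h>
using namespace Rcpp;

// Maximum one-to-one matching between two sorted integer band lists with
// |size difference| <= tol. Two-pointer greedy is optimal for 1-d interval
// matching; ties resolve toward the smaller difference by construction
// (both lists sorted, pointers only advance).
static int match_count_sorted(const IntegerVector& a, const IntegerVector& b, int tol) {
  int i = 0, j = 0, m = 0;
  const int na = a.size(), nb = b.size();
  while (i < na && j < nb) {
    int d = a[i] - b[j];
    if (d < 0) d = -d;
    if (d <= tol) { ++m; ++i; ++j; }
    else if (a[i] < b[j]) ++i;
    else ++j;
  }
  return m;
}

// [[Rcpp::export(name = ".match_count_cpp")]]
int match_count_cpp(IntegerVector a, IntegerVector b, int tol) {
  IntegerVector as = clone(a).sort();
  IntegerVector bs = clone(b).sort();
  return match_count_sorted(as, bs, tol);
}

// All-pairs shared band counts over a list of integer band vectors.
// Only pairs with count >= min_count are returned (1-based indices).
// Profiles are sorted internally.
// [[Rcpp::export(name = ".pair_match_counts_cpp")]]
DataFrame pair_match_counts_cpp(List profiles, int tol, int min_count) {
  const int n = profiles.size();
  std::vector<IntegerVector> sorted(n);
  for (int k = 0; k < n; ++k) {
    IntegerVector v = profiles[k];
    sorted[k] = clone(v).sort();
  }
  std::vector<int> ii, jj, cc;
  for (int i = 0; i < n - 1; ++i) {
    const IntegerVector& a = sorted[i];
    if (a.size() == 0) continue;
    for (int j = i + 1; j < n; ++j) {
      const IntegerVector& b = sorted[j];
      if (b.size() == 0) continue;
      int m = match_count_sorted(a, b, tol);
      if (m >= min_count) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
        cc.push_back(m);
      }
    }
  }
  return DataFrame::create(_["i"] = ii, _["j"] = jj, _["shared"] = cc);
}
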