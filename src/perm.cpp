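#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Partial Fisher-Yates draw of k positions out of n using R's RNG.
// Positions are drawn independently of the values stored at them, so two
// calls under the same seed visit the same gene labels even if the
// statistics attached to those labels differ (this is what makes sign-flip
// antisymmetry and shift monotonicity exact, not just asymptotic).
static inline void draw_positions(std::vector<int> &pool, int k,
                                  std::vector<int> &out) {
  int n = (int)pool.size();
  for (int i = 0; i < k; ++i) {
    int j = i + (int)(unif_rand() * (n - i));
    if (j >= n) j = n - 1; // guard against unif_rand() == 1.0
    std::swap(pool[i], pool[j]);
    out[i] = pool[i];
  }
}

static inline double median_of(std::vector<double> &x) {
  int k = (int)x.size();
  std::sort(x.begin(), x.end());
  return (k % 2) ? x[k / 2] : 0.5 * (x[k / 2 - 1] + x[k / 2]);
}

//' Null medians of signed and absolute statistics from shared gene draws
//'
//' For each of n_perm permutations, draws k genes without replacement from
//' the universe and returns the median of their signed statistics (column 1)
//' and of their absolute statistics (column 2), both medians taken over the
//' same drawn genes.
//'
//' @param stats numeric vector of gene-level statistics (the universe)
//' @param k number of genes to draw per permutation
//' @param n_perm number of permutations
//' @return numeric matrix n_perm x 2
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix perm_null_medians_signed_abs(NumericVector stats, int k,
                                           int n_perm) {
  int n = stats.size();
  if (k < 1 || k > n) stop("k must be in [1, length(stats)]");
  NumericMatrix out(n_perm, 2);
  std::vector<int> pool(n);
  for (int i = 0; i < n; ++i) pool[i] = i;
  std::vector<int> idx(k);
  std::vector<double> v(k), a(k);
  for (int p = 0; p < n_perm; ++p) {
    draw_positions(pool, k, idx);
    for (int i = 0; i < k; ++i) {
      v[i] = stats[idx[i]];
      a[i] = std::fabs(v[i]);
    }
    out(p, 0) = median_of(v);
    out(p, 1) = median_of(a);
  }
  return out;
}

//' Null medians from a sub-universe (mixed-directional classes)
//'
//' @param stats statistics of the sign-restricted sub-universe
//' @param k draw size per permutation
//' @param n_perm number of permutations
//' @return numeric vector of n_perm null medians
//' @keywords internal
// [[Rcpp::export]]
NumericVector perm_null_medians(NumericVector stats, int k, int n_perm) {
  int n = stats.size();
  if (k < 1 || k > n) stop("k must be in [1, length(stats)]");
  NumericVector out(n_perm);
  std::vector<int> pool(n);
  for (int i = 0; i < n; ++i) pool[i] = i;
  std::vector<int> idx(k);
  std::vector<double> v(k);
  for (int p = 0; p < n_perm; ++p) {
    draw_positions(pool, k, idx);
    for (int i = 0; i < k; ++i) v[i] = stats[idx[i]];
    out[p] = median_of(v);
  }
  return out;
}
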