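#include <Rcpp.h>
using namespace Rcpp;

// Exact two-sided permutation p-value for Spearman's rho. Works on centered
// (mid)rank vectors: rho is a strictly increasing function of
// T = sum(a_i * b_perm(i)) for fixed margins, so counting permutations with
// |T| >= |T_obs| counts permutations with |rho| >= |rho_obs|. Handles ties
// because midranks enter directly. Intended for n <= 10 (10! = 3,628,800
// permutations).
static void perm_count(std::vector<double>& a, const std::vector<double>& b,
                       int k, double partial, double tobs,
                       long long& hits, long long& total) {
  int n = (int)a.size();
  if (k == n) {
    ++total;
    if (std::fabs(partial) >= tobs) ++hits;
    return;
  }
  for (int i = k; i < n; ++i) {
    std::swap(a[k], a[i]);
    perm_count(a, b, k + 1, partial + a[k] * b[k], tobs, hits, total);
    std::swap(a[k], a[i]);
  }
}

// [[Rcpp::export(name = ".spearman_perm_p")]]
double spearman_perm_p(NumericVector ra, NumericVector rb) {
  int n = ra.size();
  if (n != rb.size()) stop("rank vectors differ in length");
  if (n > 10) stop("exact permutation limited to n <= 10");
  std::vector<double> a(n), b(n);
  double ma = 0, mb = 0;
  for (int i = 0; i < n; ++i) { ma += ra[i]; mb += rb[i]; }
  ma /= n; mb /= n;
  double tobs = 0;
  for (int i = 0; i < n; ++i) {
    a[i] = ra[i] - ma; b[i] = rb[i] - mb;
    tobs += a[i] * b[i];
  }
  // tolerance guards against |T*| == |T_obs| ties lost to rounding
  double tol = 1e-9 * (1 + std::fabs(tobs));
  long long hits = 0, total = 0;
  perm_count(a, b, 0, 0.0, std::fabs(tobs) - tol, hits, total);
  return (double)hits / (double)total;
}
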