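#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

static int greedy_shared(const int* a, int na, const int* b, int nb, int t) {
  // Two-pointer greedy over ascending band lists: advance the pointer at the
  // smaller value; pair (and advance both) when within tolerance.  Ties in
  // matching are broken smallest-size-first by construction.
  int i = 0, j = 0, m = 0;
  while (i < na && j < nb) {
    int d = a[i] - b[j];
    if (d <= t && d >= -t) { ++m; ++i; ++j; }
    else if (d < 0) ++i;
    else ++j;
  }
  return m;
}

// [[Rcpp::export(name = ".shared_bands_cpp")]]
int shared_bands_cpp(IntegerVector a, IntegerVector b, int t) {
  return greedy_shared(a.begin(), a.size(), b.begin(), b.size(), t);
}

// [[Rcpp::export(name = ".pairwise_shared_cpp")]]
IntegerMatrix pairwise_shared_cpp(List fps, int t) {
  int n = fps.size();
  std::vector<IntegerVector> v(n);
  for (int i = 0; i < n; ++i) v[i] = fps[i];
  IntegerMatrix m(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int s = greedy_shared(v[i].begin(), v[i].size(),
                            v[j].begin(), v[j].size(), t);
      m(i, j) = s;
      m(j, i) = s;
    }
    m(i, i) = v[i].size();
  }
  return m;
}

// [[Rcpp::export(name = ".match_flags_cpp")]]
LogicalVector match_flags_cpp(IntegerVector a, NumericVector b, double t) {
  // greedy one-to-one matching of sorted a against sorted b; returns for
  // each element of a whether it was paired
  int na = a.size(), nb = b.size();
  LogicalVector out(na);
  int i = 0, j = 0;
  while (i < na && j < nb) {
    double d = (double)a[i] - b[j];
    if (d <= t && d >= -t) { out[i] = true; ++i; ++j; }
    else if (d < 0) ++i;
    else ++j;
  }
  return out;
}

// [[Rcpp::export(name = ".coincidence_mc_cpp")]]
double coincidence_mc_cpp(int nL, int nH, int t, int G, int m, int trials) {
  // Monte-Carlo estimate of P(shared >= m) for two iid-uniform band lists
  // over G integer states, shared counted by the greedy one-to-one matcher.
  // Uses R's RNG so set.seed() governs reproducibility.
  std::vector<int> a(nL), b(nH);
  int hits = 0;
  for (int it = 0; it < trials; ++it) {
    for (int i = 0; i < nL; ++i) a[i] = 1 + (int)(unif_rand() * G);
    for (int i = 0; i < nH; ++i) b[i] = 1 + (int)(unif_rand() * G);
    std::sort(a.begin(), a.end());
    std::sort(b.begin(), b.end());
    if (greedy_shared(a.data(), nL, b.data(), nH, t) >= m) ++hits;
  }
  return (double)hits / (double)trials;
}
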