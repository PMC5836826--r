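#include <Rcpp.h>
using namespace Rcpp;

// Greedy leftmost matching of two sorted band lists under symmetric tolerance t.
// Each band is used at most once. For sorted inputs and symmetric tolerance this
// equals the maximum bipartite matching (checked against an exhaustive oracle in
// the test suite).
static int sb_core(const int* a, int na, const int* b, int nb, int t) {
  int i = 0, j = 0, s = 0;
  while (i < na && j < nb) {
    int d = a[i] - b[j];
    if (d < 0) d = -d;
    if (d <= t) { ++s; ++i; ++j; }
    else if (a[i] < b[j]) ++i;
    else ++j;
  }
  return s;
}

// [[Rcpp::export(name = ".sb_pair")]]
int sb_pair(IntegerVector a, IntegerVector b, int t) {
  return sb_core(INTEGER(a), a.size(), INTEGER(b), b.size(), t);
}

// All unordered pairs i < j over a list of sorted integer band vectors.
// Returns only pairs with shared >= min_shared (s = 0 can never be significant).
// [[Rcpp::export(name = ".sb_allpairs")]]
DataFrame sb_allpairs(List bands, int t, int min_shared) {
  int n = bands.size();
  std::vector<IntegerVector> v(n);
  for (int i = 0; i < n; ++i) v[i] = bands[i];
  std::vector<int> ii, jj, ss;
  for (int i = 0; i < n - 1; ++i) {
    const int* ai = INTEGER(v[i]); int na = v[i].size();
    if (na == 0) continue;
    for (int j = i + 1; j < n; ++j) {
      int nb = v[j].size();
      if (nb == 0) continue;
      // cheap range prefilter: disjoint value ranges cannot share bands
      if (ai[na - 1] + t < INTEGER(v[j])[0] || INTEGER(v[j])[nb - 1] + t < ai[0])
        continue;
      int s = sb_core(ai, na, INTEGER(v[j]), nb, t);
      if (s >= min_shared) { ii.push_back(i + 1); jj.push_back(j + 1); ss.push_back(s); }
    }
  }
  return DataFrame::create(_["i"] = ii, _["j"] = jj, _["shared"] = ss);
}

// Cross-set shared-band counts: full na x nb integer matrix (clones x windows).
// [[Rcpp::export(name = ".sb_cross")]]
IntegerMatrix sb_cross(List a, List b, int t) {
  int na = a.size(), nb = b.size();
  IntegerMatrix out(na, nb);
  std::vector<IntegerVector> va(na), vb(nb);
  for (int i = 0; i < na; ++i) va[i] = a[i];
  for (int j = 0; j < nb; ++j) vb[j] = b[j];
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j)
      out(i, j) = sb_core(INTEGER(va[i]), va[i].size(), INTEGER(vb[j]), vb[j].size(), t);
  return out;
}

// Interval-consistency violation count of an ordering (see order_violations
// in R/assembly.R for the model). ord is a 1-based permutation; adj/adjc are
// logical adjacency matrices (significant / compatible).
// [[Rcpp::export(name = ".viol_count")]]
int viol_count(IntegerVector ord, LogicalMatrix adj, LogicalMatrix adjc) {
  int n = ord.size();
  std::vector<int> pos(n + 1);
  for (int k = 0; k < n; ++k) pos[ord[k]] = k;
  int steps = 0, fwd = 0, bwd = 0;
  for (int k = 0; k + 1 < n; ++k)
    if (!adjc(ord[k] - 1, ord[k + 1] - 1)) ++steps;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (!adj(i, j)) continue;
      int lo = pos[i + 1], hi = pos[j + 1];
      if (lo > hi) std::swap(lo, hi);
      int left = ord[lo] - 1, right = ord[hi] - 1;
      for (int k = lo + 1; k < hi; ++k) {
        int m = ord[k] - 1;
        if (!adjc(m, left)) ++fwd;
        if (!adjc(m, right)) ++bwd;
      }
    }
  return steps + std::min(fwd, bwd);
}

// Clones (1-based indices) implicated in at least one violation under the
// better anchor direction.
// [[Rcpp::export(name = ".viol_clones")]]
IntegerVector viol_clones(IntegerVector ord, LogicalMatrix adj,
                          LogicalMatrix adjc) {
  int n = ord.size();
  std::vector<int> pos(n + 1);
  for (int k = 0; k < n; ++k) pos[ord[k]] = k;
  std::vector<bool> inv(n, false);
  for (int k = 0; k + 1 < n; ++k)
    if (!adjc(ord[k] - 1, ord[k + 1] - 1)) {
      inv[ord[k] - 1] = true; inv[ord[k + 1] - 1] = true;
    }
  int fwd = 0, bwd = 0;
  std::vector<int> fl, bl;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (!adj(i, j)) continue;
      int lo = pos[i + 1], hi = pos[j + 1];
      if (lo > hi) std::swap(lo, hi);
      int left = ord[lo] - 1, right = ord[hi] - 1;
      for (int k = lo + 1; k < hi; ++k) {
        int m = ord[k] - 1;
        if (!adjc(m, left)) { ++fwd; fl.push_back(left); fl.push_back(right);
          fl.push_back(m); }
        if (!adjc(m, right)) { ++bwd; bl.push_back(right); bl.push_back(left);
          bl.push_back(m); }
      }
    }
  const std::vector<int>& use = (fwd <= bwd) ? fl : bl;
  for (size_t k = 0; k < use.size(); ++k) inv[use[k]] = true;
  std::vector<int> out;
  for (int i = 0; i < n; ++i) if (inv[i]) out.push_back(i + 1);
  return wrap(out);
}
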