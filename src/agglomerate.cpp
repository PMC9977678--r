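#include <Rcpp.h>
using namespace Rcpp;

// Unweighted average-linkage (UPGMA) agglomeration of 2D points with a
// dendrogram cut: merges are realized while the smallest mean inter-cluster
// point-pair distance is <= cut (boundary inclusive). Deterministic
// tie-break: among minimal pairs the lexicographically smallest pair of
// current cluster ids wins, where a cluster's id is the smallest 0-based
// input index among its members. Clusters live in the slot of their id, so
// ascending strict-< scans realize the tie-break for free.
//
// Average linkage satisfies the reducibility property, hence merge heights
// are non-decreasing and stopping at the first minimum above the cut equals
// cutting the full tree.
//
// A per-row nearest-partner cache (row i stores its best partner j > i)
// avoids rescanning all pairs at every merge; rows are recomputed only when
// their cached partner was touched by a merge. Worst case O(n^3), typical
// O(n^2) - the standard "generic" scheme for non-monotone-safe linkages.
//
// Returns 1-based cluster labels, renumbered 1..k by ascending cluster id.

static inline double dget(const std::vector<double> &d, int n, int i, int j) {
  return d[static_cast<size_t>(i) * n + j];
}

// [[Rcpp::export(name = ".avg_linkage_cut")]]
IntegerVector avg_linkage_cut(NumericVector x, NumericVector y, double cut) {
  const int n = x.size();
  IntegerVector lab(n);
  if (n == 0) return lab;
  std::vector<double> d(static_cast<size_t>(n) * n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double v = std::sqrt(dx * dx + dy * dy);
      d[static_cast<size_t>(i) * n + j] = v;
      d[static_cast<size_t>(j) * n + i] = v;
    }
  }
  std::vector<bool> active(n, true);
  std::vector<int> sz(n, 1);
  std::vector<int> rep(n);             // current slot (= cluster id) per point
  std::vector<double> nn_val(n, R_PosInf);
  std::vector<int> nn_j(n, -1);        // best partner j > i (smallest on ties)
  for (int i = 0; i < n; ++i) rep[i] = i;

  // recompute the cached best partner of row i (over active j > i)
  auto recompute_row = [&](int i) {
    double best = R_PosInf;
    int bj = -1;
    const double *row = &d[static_cast<size_t>(i) * n];
    for (int j = i + 1; j < n; ++j) {
      if (!active[j]) continue;
      if (row[j] < best) { best = row[j]; bj = j; }
    }
    nn_val[i] = best;
    nn_j[i] = bj;
  };
  for (int i = 0; i < n; ++i) recompute_row(i);

  int n_active = n;
  while (n_active > 1) {
    double best = R_PosInf;
    int bi = -1;
    for (int i = 0; i < n; ++i) {
      if (!active[i] || nn_j[i] < 0) continue;
      if (nn_val[i] < best) { best = nn_val[i]; bi = i; }
    }
    if (best > cut) break;
    const int bj = nn_j[bi];
    // merge bj into bi (bi < bj, so the merged id stays the member minimum)
    for (int k = 0; k < n; ++k) {
      if (!active[k] || k == bi || k == bj) continue;
      double v = (sz[bi] * dget(d, n, bi, k) + sz[bj] * dget(d, n, bj, k)) /
                 (sz[bi] + sz[bj]);
      d[static_cast<size_t>(bi) * n + k] = v;
      d[static_cast<size_t>(k) * n + bi] = v;
    }
    sz[bi] += sz[bj];
    active[bj] = false;
    for (int p = 0; p < n; ++p) if (rep[p] == bj) rep[p] = bi;
    --n_active;
    // refresh caches: row bi changed wholesale; any row whose cached partner
    // was bi (distance changed) or bj (gone) is stale; rows k < bi may gain
    // a better (or equal, smaller-id) partner in the updated bi column
    recompute_row(bi);
    for (int k = 0; k < n; ++k) {
      if (!active[k] || k == bi) continue;
      if (nn_j[k] == bi || nn_j[k] == bj) {
        recompute_row(k);
      } else if (k < bi) {
        double v = dget(d, n, k, bi);
        if (v < nn_val[k] || (v == nn_val[k] && bi < nn_j[k])) {
          nn_val[k] = v;
          nn_j[k] = bi;
        }
      }
    }
  }

  // renumber cluster ids (slot indices) to 1..k preserving id order
  std::vector<int> newid(n, 0);
  int k = 0;
  for (int i = 0; i < n; ++i) if (active[i]) newid[i] = ++k;
  for (int p = 0; p < n; ++p) lab[p] = newid[rep[p]];
  return lab;
}
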