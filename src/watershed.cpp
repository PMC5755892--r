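#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Union-find with path halving.
static inline int find_root(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Priority-flood watershed of a 2D surface with dynamics-based basin merging.
//
// Pixels are flooded in increasing order of surface height. A pixel with no
// assigned 4-neighbour opens a new basin; a pixel adjacent to a single basin
// joins it; where several basins meet, any basin whose dynamics (current
// water level minus its minimum) is below merge_depth is absorbed into the
// deepest of the meeting basins, and the saddle pixel itself is assigned to
// the deepest surviving basin. Barrier pixels are raised above the global
// maximum so they flood last and attach to an adjacent basin, keeping the
// partition complete. Every pixel receives exactly one label >= 1.
//
// Merging by dynamics is the flooding-order equivalent of imposing h-minima
// markers with h = merge_depth: shallow minima (noise) cannot survive as
// separate basins, deep cavities can.
// [[Rcpp::export(name = ".ws_flood")]]
IntegerMatrix ws_flood(NumericMatrix surface, LogicalMatrix barrier,
                       double merge_depth) {
  const int nr = surface.nrow(), nc = surface.ncol();
  const int n = nr * nc;
  if (barrier.nrow() != nr || barrier.ncol() != nc)
    stop("barrier mask must match surface dimensions");

  std::vector<double> v(n);
  double vmax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    v[i] = surface[i];
    if (!R_finite(v[i])) stop("surface values must be finite");
    if (v[i] > vmax) vmax = v[i];
  }
  for (int i = 0; i < n; ++i)
    if (barrier[i]) v[i] = vmax + 1.0;

  // stable ascending order; ties broken by linear (column-major) index
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&v](int a, int b) { return v[a] < v[b] || (v[a] == v[b] && a < b); });

  std::vector<int> label(n, 0);          // 0 = unassigned
  std::vector<int> parent;               // union-find over basin ids (1-based)
  std::vector<double> bmin;              // basin minimum per id
  parent.push_back(0);                   // dummy id 0
  bmin.push_back(0.0);

  std::vector<int> roots;
  roots.reserve(4);

  for (int k = 0; k < n; ++k) {
    const int p = ord[k];
    const int r = p % nr, c = p / nr;
    roots.clear();
    const int nb[4] = {
      (r > 0) ? p - 1 : -1, (r < nr - 1) ? p + 1 : -1,
      (c > 0) ? p - nr : -1, (c < nc - 1) ? p + nr : -1};
    for (int j = 0; j < 4; ++j) {
      const int q = nb[j];
      if (q >= 0 && label[q] != 0) {
        int rt = find_root(parent, label[q]);
        bool seen = false;
        for (size_t t = 0; t < roots.size(); ++t)
          if (roots[t] == rt) { seen = true; break; }
        if (!seen) roots.push_back(rt);
      }
    }
    if (roots.empty()) {
      // new regional minimum: open a basin
      parent.push_back((int)parent.size());
      bmin.push_back(v[p]);
      label[p] = (int)parent.size() - 1;
    } else if (roots.size() == 1) {
      label[p] = roots[0];
    } else {
      // saddle: deepest basin wins; ties by smaller id (older basin)
      int deepest = roots[0];
      for (size_t t = 1; t < roots.size(); ++t)
        if (bmin[roots[t]] < bmin[deepest] ||
            (bmin[roots[t]] == bmin[deepest] && roots[t] < deepest))
          deepest = roots[t];
      for (size_t t = 0; t < roots.size(); ++t) {
        const int rt = roots[t];
        if (rt == deepest) continue;
        if (v[p] - bmin[rt] < merge_depth) {
          parent[rt] = deepest;          // absorb shallow basin
          if (bmin[rt] < bmin[deepest]) bmin[deepest] = bmin[rt];
        }
      }
      label[p] = deepest;
    }
  }

  // compact labels to 1..K in order of basin creation
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  IntegerMatrix out(nr, nc);
  for (size_t id = 1; id < parent.size(); ++id) {
    int rt = find_root(parent, (int)id);
    if (remap[rt] == 0 && (size_t)rt == id) remap[rt] = ++next;
  }
  // roots may have been absorbed after pixels were labelled with them
  for (int i = 0; i < n; ++i) {
    int rt = find_root(parent, label[i]);
    if (remap[rt] == 0) remap[rt] = ++next;
    out[i] = remap[rt];
  }
  return out;
}
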