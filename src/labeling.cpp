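#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Two-pass connected-component labeling of a logical mask.
// connectivity: 4 or 8. Labels are 1..k in raster order of first occurrence;
// background is 0.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(1024);
  parent.push_back(0); // dummy so labels start at 1

  const bool diag = (connectivity == 8);

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int best = 0;
      int neigh[4];
      int nn = 0;
      // previously visited neighbours (column-major scan): up, left,
      // and for 8-connectivity the two left diagonals
      if (r > 0 && mask(r - 1, c)) neigh[nn++] = lab(r - 1, c);
      if (c > 0 && mask(r, c - 1)) neigh[nn++] = lab(r, c - 1);
      if (diag && c > 0) {
        if (r > 0 && mask(r - 1, c - 1)) neigh[nn++] = lab(r - 1, c - 1);
        if (r + 1 < nr && mask(r + 1, c - 1)) neigh[nn++] = lab(r + 1, c - 1);
      }
      for (int i = 0; i < nn; ++i)
        if (best == 0 || neigh[i] < best) best = neigh[i];
      if (best == 0) {
        int newlab = (int)parent.size();
        parent.push_back(newlab);
        lab(r, c) = newlab;
      } else {
        lab(r, c) = best;
        for (int i = 0; i < nn; ++i) uf_union(parent, best, neigh[i]);
      }
    }
  }

  // second pass: flatten and renumber consecutively
  std::vector<int> newlab(parent.size(), 0);
  int k = 0;
  for (size_t i = 1; i < parent.size(); ++i) {
    int root = uf_find(parent, (int)i);
    if (newlab[root] == 0 && (size_t)root == i) newlab[root] = ++k;
  }
  // roots found above in index order; assign non-roots
  for (size_t i = 1; i < parent.size(); ++i) {
    int root = uf_find(parent, (int)i);
    if (newlab[root] == 0) newlab[root] = ++k;
    newlab[i] = newlab[root];
  }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0) lab(r, c) = newlab[lab(r, c)];

  return lab;
}
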