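#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Two-pass 8-connected component labelling with union-find.

static int uf_find(std::vector<int> &parent, int a) {
  while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
  return a;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0); // label 0 = background sentinel
  int next = 1;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      // previously-scanned 8-neighbors: (r-1,c), (r-1,c-1), (r,c-1), (r+1,c-1)
      int nb[4] = {0, 0, 0, 0};
      if (r > 0)               nb[0] = lab(r - 1, c);
      if (r > 0 && c > 0)      nb[1] = lab(r - 1, c - 1);
      if (c > 0)               nb[2] = lab(r, c - 1);
      if (r < nr - 1 && c > 0) nb[3] = lab(r + 1, c - 1);
      int lmin = 0;
      for (int k = 0; k < 4; ++k)
        if (nb[k] > 0 && (lmin == 0 || nb[k] < lmin)) lmin = nb[k];
      if (lmin == 0) {
        lab(r, c) = next;
        parent.push_back(next);
        ++next;
      } else {
        lab(r, c) = lmin;
        for (int k = 0; k < 4; ++k)
          if (nb[k] > 0) uf_union(parent, nb[k], lmin);
      }
    }
  }

  // resolve + compact to contiguous labels
  std::vector<int> remap(next, 0);
  int out = 0;
  for (int l = 1; l < next; ++l) {
    int root = uf_find(parent, l);
    if (remap[root] == 0) remap[root] = ++out;
    remap[l] = remap[root];
  }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0) lab(r, c) = remap[lab(r, c)];
  return lab;
}
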