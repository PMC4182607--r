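#include <Rcpp.h>
using namespace Rcpp;

// Two-pass union-find connected-component labeling, 8-connectivity.
// Labels are compact, 1..k, assigned in column-major scan order.

static int uf_find(std::vector<int>& parent, int a) {
  while (parent[a] != a) {
    parent[a] = parent[parent[a]];
    a = parent[a];
  }
  return a;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  a = uf_find(parent, a);
  b = uf_find(parent, b);
  if (a < b) parent[b] = a; else if (b < a) parent[a] = b;
}

// [[Rcpp::export]]
IntegerMatrix cc_label8(LogicalMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0); // label 0 = background, unused

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!x(r, c)) continue;
      // neighbors already scanned in column-major order
      const int nb[4][2] = {{r - 1, c}, {r - 1, c - 1}, {r, c - 1}, {r + 1, c - 1}};
      int cur = 0;
      for (int k = 0; k < 4; ++k) {
        const int rr = nb[k][0], cc = nb[k][1];
        if (rr < 0 || rr >= nr || cc < 0) continue;
        const int l = lab(rr, cc);
        if (l > 0) {
          if (cur == 0) cur = l; else if (cur != l) uf_union(parent, cur, l);
        }
      }
      if (cur == 0) {
        cur = (int)parent.size();
        parent.push_back(cur);
      }
      lab(r, c) = cur;
    }
  }

  // compress labels to 1..k in first-appearance order
  std::vector<int> remap(parent.size(), 0);
  int k = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      l = uf_find(parent, l);
      if (remap[l] == 0) remap[l] = ++k;
      lab(r, c) = remap[l];
    }
  }
  return lab;
}
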