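#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Label connected components of the pixels of `x` equal to `fg`.
// connectivity is 4 or 8. Returns an integer matrix: 0 where x != fg,
// labels 1..k elsewhere, in raster order of first appearance.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(IntegerMatrix x, int fg, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = x.nrow(), nc = x.ncol(), n = nr * nc;
  std::vector<int> parent(n);
  std::vector<bool> is_fg(n);
  for (int i = 0; i < n; ++i) {
    parent[i] = i;
    is_fg[i] = (x[i] == fg);
  }
  // column-major storage: index = r + c * nr
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const int i = r + c * nr;
      if (!is_fg[i]) continue;
      if (r > 0 && is_fg[i - 1]) uf_union(parent, i, i - 1);
      if (c > 0 && is_fg[i - nr]) uf_union(parent, i, i - nr);
      if (connectivity == 8 && c > 0) {
        if (r > 0 && is_fg[i - nr - 1]) uf_union(parent, i, i - nr - 1);
        if (r < nr - 1 && is_fg[i - nr + 1]) uf_union(parent, i, i - nr + 1);
      }
    }
  }
  IntegerMatrix out(nr, nc);
  std::vector<int> relabel(n, 0);
  int next = 0;
  // raster order = row-major scan for stable, human-readable label order
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      const int i = r + c * nr;
      if (!is_fg[i]) { out[i] = 0; continue; }
      const int root = uf_find(parent, i);
      if (relabel[root] == 0) relabel[root] = ++next;
      out[i] = relabel[root];
    }
  }
  return out;
}
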