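#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling by union-find with path compression.
// The array is column-major with dims (n1, n2, n3) = (z, y, x); a single
// raster pass unions each foreground voxel with its already-visited
// neighbors, then labels are renumbered 1..n in first-voxel raster order so
// label IDs are deterministic across platforms.

static inline int find_root(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static inline void do_union(std::vector<int> &parent, int a, int b) {
  int ra = find_root(parent, a), rb = find_root(parent, b);
  if (ra != rb) {
    // attach larger root id under smaller so roots trend to earliest voxel
    if (ra < rb) parent[rb] = ra; else parent[ra] = rb;
  }
}

// [[Rcpp::export]]
IntegerVector cc_label_3d(IntegerVector mask, IntegerVector dims,
                          int connectivity) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // previous-neighbor offsets (strictly lower linear index)
  std::vector<int> d1s, d2s, d3s;
  for (int d3 = -1; d3 <= 1; ++d3)
    for (int d2 = -1; d2 <= 1; ++d2)
      for (int d1 = -1; d1 <= 1; ++d1) {
        int ord = std::abs(d1) + std::abs(d2) + std::abs(d3);
        if (ord == 0) continue;
        if (connectivity == 6 && ord > 1) continue;
        if (connectivity == 18 && ord > 2) continue;
        bool prev = (d3 < 0) || (d3 == 0 && d2 < 0) ||
                    (d3 == 0 && d2 == 0 && d1 < 0);
        if (!prev) continue;
        d1s.push_back(d1); d2s.push_back(d2); d3s.push_back(d3);
      }
  const int noff = (int)d1s.size();

  std::vector<int> parent(n);
  for (R_xlen_t i = 0; i < n; ++i) parent[i] = (int)i;

  R_xlen_t i = 0;
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2)
      for (int i1 = 0; i1 < n1; ++i1, ++i) {
        if (mask[i] == 0) continue;
        for (int k = 0; k < noff; ++k) {
          int j1 = i1 + d1s[k], j2 = i2 + d2s[k], j3 = i3 + d3s[k];
          if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3)
            continue;
          R_xlen_t j = (R_xlen_t)j1 + (R_xlen_t)n1 * (j2 + (R_xlen_t)n2 * j3);
          if (mask[j] != 0) do_union(parent, (int)i, (int)j);
        }
      }

  IntegerVector out(n);
  std::vector<int> newlab(n, 0);
  int next = 0;
  for (R_xlen_t k = 0; k < n; ++k) {
    if (mask[k] == 0) { out[k] = 0; continue; }
    int r = find_root(parent, (int)k);
    if (newlab[r] == 0) newlab[r] = ++next;
    out[k] = newlab[r];
  }
  out.attr("n_components") = next;
  return out;
}
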