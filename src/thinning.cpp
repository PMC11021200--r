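#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Topology-preserving sequential thinning of a 3D binary volume down to a
// one-voxel-thick skeleton. A border voxel is deleted only if it is a
// "simple point" (deletion preserves both the 26-connectivity of the
// foreground and the 6-connectivity of the background in its 3x3x3
// neighborhood) and not a curve endpoint. Deletion is sequential with
// re-verification at deletion time, in six directional sub-iterations
// (top/bottom/north/south/east/west borders) so material is eroded
// symmetrically toward the centerline.

// Neighborhood positions: idx = (a+1) + 3*(b+1) + 9*(c+1), a,b,c in {-1,0,1};
// center is idx 13.

static int POS[27][3];
static bool pos_init = false;

static void init_pos() {
  if (pos_init) return;
  for (int c = -1; c <= 1; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        int idx = (a + 1) + 3 * (b + 1) + 9 * (c + 1);
        POS[idx][0] = a; POS[idx][1] = b; POS[idx][2] = c;
      }
  pos_init = true;
}

static inline int cheb(int i, int j) {
  int d0 = std::abs(POS[i][0] - POS[j][0]);
  int d1 = std::abs(POS[i][1] - POS[j][1]);
  int d2 = std::abs(POS[i][2] - POS[j][2]);
  return std::max(d0, std::max(d1, d2));
}

static inline int manh(int i, int j) {
  return std::abs(POS[i][0] - POS[j][0]) + std::abs(POS[i][1] - POS[j][1]) +
         std::abs(POS[i][2] - POS[j][2]);
}

// number of 26-connected components of the foreground among the 26 neighbors
static int n26_components(const bool fg[27]) {
  bool seen[27] = {false};
  int ncomp = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !fg[s] || seen[s]) continue;
    ++ncomp;
    int stack[27], top = 0;
    stack[top++] = s; seen[s] = true;
    while (top > 0) {
      int u = stack[--top];
      for (int v = 0; v < 27; ++v) {
        if (v == 13 || v == u || !fg[v] || seen[v]) continue;
        if (cheb(u, v) == 1) { seen[v] = true; stack[top++] = v; }
      }
    }
  }
  return ncomp;
}

// number of 6-connected components of the background within the
// 18-neighborhood that touch a face neighbor of the center
static int n6_bg_components(const bool fg[27]) {
  bool in18[27], bg[27], seen[27] = {false};
  for (int i = 0; i < 27; ++i) {
    int ord = std::abs(POS[i][0]) + std::abs(POS[i][1]) + std::abs(POS[i][2]);
    in18[i] = (i != 13) && ord <= 2;
    bg[i] = in18[i] && !fg[i];
  }
  int ncomp = 0;
  for (int s = 0; s < 27; ++s) {
    if (!bg[s] || seen[s]) continue;
    // flood the 6-connected background component within the 18-neighborhood
    int stack[27], top = 0;
    stack[top++] = s; seen[s] = true;
    bool touches_face = false;
    std::vector<int> comp;
    while (top > 0) {
      int u = stack[--top];
      comp.push_back(u);
      if (manh(u, 13) == 1) touches_face = true;
      for (int v = 0; v < 27; ++v) {
        if (!bg[v] || seen[v]) continue;
        if (manh(u, v) == 1) { seen[v] = true; stack[top++] = v; }
      }
    }
    if (touches_face) ++ncomp;
  }
  return ncomp;
}

static inline bool is_simple(const bool fg[27]) {
  return n26_components(fg) == 1 && n6_bg_components(fg) == 1;
}

static inline int count_fg_neighbors(const bool fg[27]) {
  int n = 0;
  for (int i = 0; i < 27; ++i)
    if (i != 13 && fg[i]) ++n;
  return n;
}

// [[Rcpp::export]]
IntegerVector thin_3d(IntegerVector mask, IntegerVector dims) {
  init_pos();
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != n) stop("mask length does not match dims");

  std::vector<char> vol(n);
  for (R_xlen_t i = 0; i < n; ++i) vol[i] = mask[i] != 0;

  // face-neighbor linear offsets per direction (z-, z+, y-, y+, x-, x+)
  const int dir_d[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                           {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};

  auto get_nbhd = [&](int i1, int i2, int i3, bool fg[27]) {
    for (int k = 0; k < 27; ++k) {
      int j1 = i1 + POS[k][0], j2 = i2 + POS[k][1], j3 = i3 + POS[k][2];
      if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3) {
        fg[k] = false;  // outside the array counts as background
      } else {
        fg[k] = vol[(R_xlen_t)j1 + (R_xlen_t)n1 * (j2 + (R_xlen_t)n2 * j3)] != 0;
      }
    }
  };

  bool changed = true;
  std::vector<R_xlen_t> cand;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      cand.clear();
      R_xlen_t i = 0;
      for (int i3 = 0; i3 < n3; ++i3)
        for (int i2 = 0; i2 < n2; ++i2)
          for (int i1 = 0; i1 < n1; ++i1, ++i) {
            if (!vol[i]) continue;
            // border in this direction, with foreground on the opposite
            // side: structures already one voxel thick along this axis are
            // never candidates, which stops a sub-iteration from unzipping
            // a thin ribbon end-to-end
            int j1 = i1 + dir_d[dir][0], j2 = i2 + dir_d[dir][1],
                j3 = i3 + dir_d[dir][2];
            bool border;
            if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3)
              border = true;
            else
              border = !vol[(R_xlen_t)j1 + (R_xlen_t)n1 * (j2 + (R_xlen_t)n2 * j3)];
            if (!border) continue;
            int k1 = i1 - dir_d[dir][0], k2 = i2 - dir_d[dir][1],
                k3 = i3 - dir_d[dir][2];
            bool opp_fg = false;
            if (k1 >= 0 && k1 < n1 && k2 >= 0 && k2 < n2 && k3 >= 0 && k3 < n3)
              opp_fg = vol[(R_xlen_t)k1 + (R_xlen_t)n1 * (k2 + (R_xlen_t)n2 * k3)] != 0;
            if (opp_fg) cand.push_back(i);
          }
      // sequential deletion with re-check preserves topology exactly
      for (R_xlen_t ci = 0; ci < (R_xlen_t)cand.size(); ++ci) {
        R_xlen_t idx = cand[ci];
        if (!vol[idx]) continue;
        int i1 = (int)(idx % n1);
        int i2 = (int)((idx / n1) % n2);
        int i3 = (int)(idx / ((R_xlen_t)n1 * n2));
        // re-verify the directional condition on the current state
        int k1 = i1 - dir_d[dir][0], k2 = i2 - dir_d[dir][1],
            k3 = i3 - dir_d[dir][2];
        bool opp_fg = false;
        if (k1 >= 0 && k1 < n1 && k2 >= 0 && k2 < n2 && k3 >= 0 && k3 < n3)
          opp_fg = vol[(R_xlen_t)k1 + (R_xlen_t)n1 * (k2 + (R_xlen_t)n2 * k3)] != 0;
        if (!opp_fg) continue;
        bool fg[27];
        get_nbhd(i1, i2, i3, fg);
        if (count_fg_neighbors(fg) <= 1) continue;  // endpoint or isolated
        if (is_simple(fg)) {
          vol[idx] = 0;
          changed = true;
        }
      }
    }
  }

  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = vol[i] ? 1 : 0;
  return out;
}
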