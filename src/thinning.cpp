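// Topology-preserving 3D thinning to a curve skeleton, by directional
// sub-iterations: each pass visits the six face directions in turn and
// sequentially deletes voxels whose neighbor in that direction is
// background, provided the voxel is "simple" (deletion preserves both the
// 26-connectivity of the foreground and the 6-connectivity of the
// background) and is not a curve endpoint. Directional borders erode at
// most one voxel layer per pass, so tube ends retract only by about one
// radius before the centerline forms and its endpoints become protected.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <tuple>
using namespace Rcpp;

static inline long lidx(int i, int j, int k, int nx, int ny) {
  return i + (long)nx * (j + (long)ny * k);
}

// offsets of the 3x3x3 neighborhood, local index n = (di+1)+3(dj+1)+9(dk+1)
static inline int loc(int di, int dj, int dk) {
  return (di + 1) + 3 * (dj + 1) + 9 * (dk + 1);
}

// Condition A: exactly one 26-component among the 26 foreground neighbors.
static int fg_components26(const bool* nb) {
  bool seen[27] = {false};
  int comps = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comps;
    if (comps > 1) return comps;
    // BFS within the 26 neighbors
    std::queue<int> q;
    q.push(s);
    seen[s] = true;
    while (!q.empty()) {
      int v = q.front(); q.pop();
      int vi = v % 3 - 1, vj = (v / 3) % 3 - 1, vk = v / 9 - 1;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int i = vi + di, j = vj + dj, k = vk + dk;
            if (i < -1 || i > 1 || j < -1 || j > 1 || k < -1 || k > 1) continue;
            int w = loc(i, j, k);
            if (w == 13 || w == v) continue;
            if (nb[w] && !seen[w]) { seen[w] = true; q.push(w); }
          }
    }
  }
  return comps;
}

// Condition B: exactly one 6-component of background within the 18-neighborhood
// that touches a 6-neighbor of the center.
static int bg_components6(const bool* nb) {
  bool in18[27], seen[27] = {false};
  for (int s = 0; s < 27; ++s) {
    int di = s % 3 - 1, dj = (s / 3) % 3 - 1, dk = s / 9 - 1;
    int man = std::abs(di) + std::abs(dj) + std::abs(dk);
    in18[s] = (man >= 1 && man <= 2);
  }
  int comps = 0;
  for (int s = 0; s < 27; ++s) {
    if (!in18[s] || nb[s] || seen[s]) continue;
    int di = s % 3 - 1, dj = (s / 3) % 3 - 1, dk = s / 9 - 1;
    if (std::abs(di) + std::abs(dj) + std::abs(dk) != 1) continue;  // must start at a 6-neighbor
    ++comps;
    if (comps > 1) return comps;
    std::queue<int> q;
    q.push(s);
    seen[s] = true;
    while (!q.empty()) {
      int v = q.front(); q.pop();
      int vi = v % 3 - 1, vj = (v / 3) % 3 - 1, vk = v / 9 - 1;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int u = 0; u < 6; ++u) {
        int i = vi + d6[u][0], j = vj + d6[u][1], k = vk + d6[u][2];
        if (i < -1 || i > 1 || j < -1 || j > 1 || k < -1 || k > 1) continue;
        int w = loc(i, j, k);
        if (w == 13) continue;
        if (in18[w] && !nb[w] && !seen[w]) { seen[w] = true; q.push(w); }
      }
    }
  }
  return comps;
}

// [[Rcpp::export(name = ".skeletonize3d")]]
LogicalVector skeletonize3d(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long ntot = (long)nx * ny * nz;
  std::vector<char> fg(ntot);
  std::vector<long> active;
  for (long i = 0; i < ntot; ++i) {
    fg[i] = mask[i] ? 1 : 0;
    if (fg[i]) active.push_back(i);
  }
  const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  bool nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      // candidates: currently-foreground voxels whose `dir` neighbor is
      // background at the start of this sub-iteration
      std::vector<long> cand;
      for (size_t a = 0; a < active.size(); ++a) {
        long v = active[a];
        if (!fg[v]) continue;
        int vi = (int)(v % nx), vj = (int)((v / nx) % ny),
            vk = (int)(v / ((long)nx * ny));
        int i = vi + d6[dir][0], j = vj + d6[dir][1], k = vk + d6[dir][2];
        bool bgn = (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) ||
                   !fg[lidx(i, j, k, nx, ny)];
        if (bgn) cand.push_back(v);
      }
      // sequential deletion with re-check (raster order: deterministic)
      for (size_t c = 0; c < cand.size(); ++c) {
        long v = cand[c];
        if (!fg[v]) continue;
        int vi = (int)(v % nx), vj = (int)((v / nx) % ny),
            vk = (int)(v / ((long)nx * ny));
        int nfg = 0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              int s = loc(di, dj, dk);
              int i = vi + di, j = vj + dj, k = vk + dk;
              bool val = false;
              if (i >= 0 && i < nx && j >= 0 && j < ny && k >= 0 && k < nz)
                val = fg[lidx(i, j, k, nx, ny)] != 0;
              nb[s] = val;
              if (s != 13 && val) ++nfg;
            }
        if (nfg <= 1) continue;                   // curve endpoint: keep
        if (fg_components26(nb) != 1) continue;   // would split the object
        if (bg_components6(nb) != 1) continue;    // would merge/create cavities
        fg[v] = 0;
        changed = true;
      }
    }
    // compact the active list
    std::vector<long> still;
    for (size_t a = 0; a < active.size(); ++a)
      if (fg[active[a]]) still.push_back(active[a]);
    active.swap(still);
  }
  LogicalVector out(ntot);
  for (long i = 0; i < ntot; ++i) out[i] = fg[i] != 0;
  out.attr("dim") = dim;
  return out;
}
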