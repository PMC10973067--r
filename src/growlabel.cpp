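// Seeded region growing (per-seed intensity bands) and connected-component
// labelling, both over 26-neighborhoods.
#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

static inline long lidx(int i, int j, int k, int nx, int ny) {
  return i + (long)nx * (j + (long)ny * k);
}

// Breadth-first flood fill from each seed independently; a voxel is admitted
// by seed s iff it is reachable from s through voxels whose intensity lies in
// [I_s (1 - tol), I_s (1 + tol)]. The returned mask is the union over seeds.
// seeds: n x 3 matrix of 1-based voxel indices.
// [[Rcpp::export(name = ".region_grow")]]
LogicalVector region_grow(NumericVector vol, IntegerVector dim,
                          IntegerMatrix seeds, double tol) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long ntot = (long)nx * ny * nz;
  std::vector<char> mask(ntot, 0), visited(ntot, 0);
  for (int s = 0; s < seeds.nrow(); ++s) {
    int si = seeds(s, 0) - 1, sj = seeds(s, 1) - 1, sk = seeds(s, 2) - 1;
    if (si < 0 || si >= nx || sj < 0 || sj >= ny || sk < 0 || sk >= nz)
      stop("seed %d is out of bounds", s + 1);
    double iref = vol[lidx(si, sj, sk, nx, ny)];
    double lo = iref - tol * std::fabs(iref);
    double hi = iref + tol * std::fabs(iref);
    std::fill(visited.begin(), visited.end(), 0);
    std::queue<long> q;
    long s0 = lidx(si, sj, sk, nx, ny);
    visited[s0] = 1;
    mask[s0] = 1;  // seeds always belong to the mask
    if (vol[s0] >= lo && vol[s0] <= hi) q.push(s0);
    while (!q.empty()) {
      long v = q.front(); q.pop();
      int vi = (int)(v % nx), vj = (int)((v / nx) % ny), vk = (int)(v / ((long)nx * ny));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int i = vi + di, j = vj + dj, k = vk + dk;
            if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) continue;
            long w = lidx(i, j, k, nx, ny);
            if (visited[w]) continue;
            visited[w] = 1;
            if (vol[w] >= lo && vol[w] <= hi) {
              mask[w] = 1;
              q.push(w);
            }
          }
    }
  }
  LogicalVector out(ntot);
  for (long i = 0; i < ntot; ++i) out[i] = mask[i] != 0;
  out.attr("dim") = dim;
  return out;
}

// 26-connected component labelling; labels are assigned in raster-scan order
// of each component's first voxel (deterministic). 0 = background.
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long ntot = (long)nx * ny * nz;
  IntegerVector lab(ntot, 0);
  int next = 0;
  std::queue<long> q;
  for (long v0 = 0; v0 < ntot; ++v0) {
    if (!mask[v0] || lab[v0] != 0) continue;
    ++next;
    lab[v0] = next;
    q.push(v0);
    while (!q.empty()) {
      long v = q.front(); q.pop();
      int vi = (int)(v % nx), vj = (int)((v / nx) % ny), vk = (int)(v / ((long)nx * ny));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int i = vi + di, j = vj + dj, k = vk + dk;
            if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) continue;
            long w = lidx(i, j, k, nx, ny);
            if (mask[w] && lab[w] == 0) {
              lab[w] = next;
              q.push(w);
            }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
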