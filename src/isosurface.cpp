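// Isosurface extraction on a scalar voxel grid by marching cubes in its
// tetrahedral-decomposition variant: every cell is split into six tetrahedra
// sharing the main diagonal (Kuhn subdivision, consistent across neighboring
// cells), so the extracted triangulation is guaranteed watertight, with
// vertices placed by linear interpolation along grid edges.
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

struct MeshAcc {
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;  // 0-based triples
  std::unordered_map<uint64_t, int> edge_vertex;
  long ntot;
};

static int edge_point(MeshAcc& m, long ga, long gb, double fa, double fb,
                      double iso, const double* pa, const double* pb) {
  if (ga > gb) { std::swap(ga, gb); std::swap(fa, fb); std::swap(pa, pb); }
  uint64_t key = (uint64_t)ga * (uint64_t)m.ntot + (uint64_t)gb;
  std::unordered_map<uint64_t, int>::iterator it = m.edge_vertex.find(key);
  if (it != m.edge_vertex.end()) return it->second;
  double t = (iso - fa) / (fb - fa);
  int id = (int)m.vx.size();
  m.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
  m.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
  m.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
  m.edge_vertex[key] = id;
  return id;
}

static void emit_tri(MeshAcc& m, int a, int b, int c,
                     const double* inward) {
  if (a == b || b == c || a == c) return;
  // orient so the normal points away from the inside of the surface
  double ux = m.vx[b] - m.vx[a], uy = m.vy[b] - m.vy[a], uz = m.vz[b] - m.vz[a];
  double wx = m.vx[c] - m.vx[a], wy = m.vy[c] - m.vy[a], wz = m.vz[c] - m.vz[a];
  double nxv = uy * wz - uz * wy, nyv = uz * wx - ux * wz, nzv = ux * wy - uy * wx;
  double d = nxv * inward[0] + nyv * inward[1] + nzv * inward[2];
  if (d > 0) std::swap(b, c);
  m.tri.push_back(a); m.tri.push_back(b); m.tri.push_back(c);
}

// process one tetrahedron with grid indices g[4], values f[4], positions p[4][3]
static void do_tet(MeshAcc& m, const long* g, const double* f,
                   const double (*p)[3], double iso) {
  bool in[4];
  int nin = 0;
  for (int i = 0; i < 4; ++i) { in[i] = f[i] > iso; if (in[i]) ++nin; }
  if (nin == 0 || nin == 4) return;
  int ii[4], oo[4], ni = 0, no = 0;
  for (int i = 0; i < 4; ++i) { if (in[i]) ii[ni++] = i; else oo[no++] = i; }
  // direction from inside centroid toward outside centroid
  double cin[3] = {0, 0, 0}, cout[3] = {0, 0, 0}, inward[3];
  for (int i = 0; i < ni; ++i)
    for (int d = 0; d < 3; ++d) cin[d] += p[ii[i]][d] / ni;
  for (int i = 0; i < no; ++i)
    for (int d = 0; d < 3; ++d) cout[d] += p[oo[i]][d] / no;
  for (int d = 0; d < 3; ++d) inward[d] = cin[d] - cout[d];
  if (nin == 1) {
    int a = ii[0];
    int v0 = edge_point(m, g[a], g[oo[0]], f[a], f[oo[0]], iso, p[a], p[oo[0]]);
    int v1 = edge_point(m, g[a], g[oo[1]], f[a], f[oo[1]], iso, p[a], p[oo[1]]);
    int v2 = edge_point(m, g[a], g[oo[2]], f[a], f[oo[2]], iso, p[a], p[oo[2]]);
    emit_tri(m, v0, v1, v2, inward);
  } else if (nin == 3) {
    int a = oo[0];
    int v0 = edge_point(m, g[a], g[ii[0]], f[a], f[ii[0]], iso, p[a], p[ii[0]]);
    int v1 = edge_point(m, g[a], g[ii[1]], f[a], f[ii[1]], iso, p[a], p[ii[1]]);
    int v2 = edge_point(m, g[a], g[ii[2]], f[a], f[ii[2]], iso, p[a], p[ii[2]]);
    emit_tri(m, v0, v1, v2, inward);
  } else {
    int a = ii[0], b = ii[1], c = oo[0], d = oo[1];
    int vac = edge_point(m, g[a], g[c], f[a], f[c], iso, p[a], p[c]);
    int vad = edge_point(m, g[a], g[d], f[a], f[d], iso, p[a], p[d]);
    int vbd = edge_point(m, g[b], g[d], f[b], f[d], iso, p[b], p[d]);
    int vbc = edge_point(m, g[b], g[c], f[b], f[c], iso, p[b], p[c]);
    emit_tri(m, vac, vad, vbd, inward);
    emit_tri(m, vac, vbd, vbc, inward);
  }
}

// [[Rcpp::export(name = ".march_tets")]]
List march_tets(NumericVector field, IntegerVector dim, double iso,
                double spacing, NumericVector origin) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  MeshAcc m;
  m.ntot = (long)nx * ny * nz;
  // corner offsets of a cell
  const int co[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                        {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  // Kuhn subdivision: six tets sharing the main diagonal 0-6
  const int tets[6][4] = {{0,1,2,6},{0,2,3,6},{0,3,7,6},
                          {0,7,4,6},{0,4,5,6},{0,5,1,6}};
  double fv[8], pv[8][3];
  long gv[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + co[c][0], cj = j + co[c][1], ck = k + co[c][2];
          long g = ci + (long)nx * (cj + (long)ny * ck);
          double f = field[g];
          if (f == iso) f = iso + 1e-9 * (std::fabs(iso) + 1.0);
          gv[c] = g;
          fv[c] = f;
          pv[c][0] = origin[0] + ci * spacing;
          pv[c][1] = origin[1] + cj * spacing;
          pv[c][2] = origin[2] + ck * spacing;
          if (f > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          long g4[4];
          double f4[4], p4[4][3];
          for (int u = 0; u < 4; ++u) {
            int c = tets[t][u];
            g4[u] = gv[c];
            f4[u] = fv[c];
            for (int d = 0; d < 3; ++d) p4[u][d] = pv[c][d];
          }
          do_tet(m, g4, f4, p4, iso);
        }
      }
  int nv = (int)m.vx.size(), nt = (int)m.tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = m.vx[i]; V(i, 1) = m.vy[i]; V(i, 2) = m.vz[i];
  }
  IntegerMatrix Tm(nt, 3);
  for (int i = 0; i < nt; ++i)
    for (int d = 0; d < 3; ++d) Tm(i, d) = m.tri[3 * i + d] + 1;  // 1-based
  return List::create(_["vertices"] = V, _["triangles"] = Tm);
}
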