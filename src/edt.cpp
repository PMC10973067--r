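// Exact Euclidean distance transform (squared), Felzenszwalb-Huttenlocher
// lower-envelope algorithm applied separably along the three axes.
#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::max() / 4.0;

static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (in voxel units) from each foreground voxel to
// the nearest background voxel center. Background voxels get 0.
// [[Rcpp::export(name = ".sq_edt")]]
NumericVector sq_edt(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long ntot = (long)nx * ny * nz;
  std::vector<double> d(ntot);
  for (long i = 0; i < ntot; ++i) d[i] = mask[i] ? INF : 0.0;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x axis
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      long base = (long)nx * (j + (long)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = d[base + i];
      dt1d(f, dd, v, z, nx);
      for (int i = 0; i < nx; ++i) d[base + i] = dd[i];
    }
  // y axis
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      long base = i + (long)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = d[base + (long)nx * j];
      dt1d(f, dd, v, z, ny);
      for (int j = 0; j < ny; ++j) d[base + (long)nx * j] = dd[j];
    }
  // z axis
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      long base = i + (long)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = d[base + (long)nx * ny * k];
      dt1d(f, dd, v, z, nz);
      for (int k = 0; k < nz; ++k) d[base + (long)nx * ny * k] = dd[k];
    }
  NumericVector out(d.begin(), d.end());
  out.attr("dim") = dim;
  return out;
}
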