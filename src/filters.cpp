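// Separable Gaussian-derivative filtering and multiscale Hessian vesselness.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sampled Gaussian-derivative correlation kernel, calibrated so that the
// discrete response to polynomials matches the analytic derivative
// (order 0: sum 1; order 1: response to x is 1; order 2: response to x^2/2 is 1).
static std::vector<double> deriv_kernel(double sigma, int order) {
  int rad = std::max(1, (int)std::ceil(4.0 * sigma));
  int n = 2 * rad + 1;
  std::vector<double> g(n), k(n);
  double s2 = sigma * sigma, gsum = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    g[i + rad] = std::exp(-0.5 * i * i / s2);
    gsum += g[i + rad];
  }
  for (int i = 0; i < n; ++i) g[i] /= gsum;
  if (order == 0) return g;
  if (order == 1) {
    double m2 = 0.0;
    for (int i = -rad; i <= rad; ++i) m2 += i * i * g[i + rad];
    for (int i = -rad; i <= rad; ++i) k[i + rad] = i * g[i + rad] / m2;
    return k;
  }
  // order == 2
  for (int i = -rad; i <= rad; ++i)
    k[i + rad] = (i * i / (s2 * s2) - 1.0 / s2) * g[i + rad];
  double mean = 0.0;
  for (int i = 0; i < n; ++i) mean += k[i];
  mean /= n;
  for (int i = 0; i < n; ++i) k[i] -= mean;
  double resp = 0.0;
  for (int i = -rad; i <= rad; ++i) resp += 0.5 * i * i * k[i + rad];
  for (int i = 0; i < n; ++i) k[i] /= resp;
  return k;
}

static inline int reflect101(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

// Correlate along one axis (0, 1 or 2) of a column-major (nx, ny, nz) array.
static void correlate_axis(const std::vector<double>& in, std::vector<double>& out,
                           int nx, int ny, int nz, int axis,
                           const std::vector<double>& k) {
  int rad = ((int)k.size() - 1) / 2;
  int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  long stride = (axis == 0) ? 1L : (axis == 1) ? (long)nx : (long)nx * ny;
  long nline = (long)nx * ny * nz / n;
  std::vector<double> line(n);
  for (long l = 0; l < nline; ++l) {
    // base index of this line
    long base;
    if (axis == 0) {
      base = l * (long)nx;
    } else if (axis == 1) {
      long i = l % nx, kz = l / nx;
      base = i + (long)nx * ny * kz;
    } else {
      base = l;
    }
    for (int t = 0; t < n; ++t) line[t] = in[base + stride * t];
    for (int t = 0; t < n; ++t) {
      double acc = 0.0;
      for (int u = -rad; u <= rad; ++u)
        acc += k[u + rad] * line[reflect101(t + u, n)];
      out[base + stride * t] = acc;
    }
  }
}

static void smooth_deriv(const std::vector<double>& in, std::vector<double>& out,
                         std::vector<double>& tmp, int nx, int ny, int nz,
                         double sigma, int ox, int oy, int oz) {
  correlate_axis(in, out, nx, ny, nz, 0, deriv_kernel(sigma, ox));
  correlate_axis(out, tmp, nx, ny, nz, 1, deriv_kernel(sigma, oy));
  correlate_axis(tmp, out, nx, ny, nz, 2, deriv_kernel(sigma, oz));
}

// Eigenvalues of a symmetric 3x3 matrix (analytic, Smith's trigonometric method).
static inline void eig3_sym(double a11, double a12, double a13,
                            double a22, double a23, double a33,
                            double& e1, double& e2, double& e3) {
  double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 < 1e-300) {
    e1 = a11; e2 = a22; e3 = a33;
  } else {
    double q = (a11 + a22 + a33) / 3.0;
    double b11 = a11 - q, b22 = a22 - q, b33 = a33 - q;
    double p2 = b11 * b11 + b22 * b22 + b33 * b33 + 2.0 * p1;
    double p = std::sqrt(p2 / 6.0);
    // det(B/p) / 2
    double c11 = b11 / p, c12 = a12 / p, c13 = a13 / p;
    double c22 = b22 / p, c23 = a23 / p, c33 = b33 / p;
    double detB = c11 * (c22 * c33 - c23 * c23) - c12 * (c12 * c33 - c23 * c13)
                + c13 * (c12 * c23 - c22 * c13);
    double r = detB / 2.0;
    r = std::max(-1.0, std::min(1.0, r));
    double phi = std::acos(r) / 3.0;
    e1 = q + 2.0 * p * std::cos(phi);
    e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    e2 = 3.0 * q - e1 - e3;
  }
  // sort by absolute value: |e1| <= |e2| <= |e3|
  double v[3] = {e1, e2, e3};
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2 - i; ++j)
      if (std::fabs(v[j]) > std::fabs(v[j + 1])) std::swap(v[j], v[j + 1]);
  e1 = v[0]; e2 = v[1]; e3 = v[2];
}

// Single-scale Hessian vesselness (tubular-structure likelihood in [0, 1]).
// c <= 0 requests the conventional auto choice: half the maximum Frobenius
// norm of the (gamma-normalized) Hessian over the volume at this scale.
// [[Rcpp::export(name = ".frangi_scale")]]
NumericVector frangi_scale(NumericVector vol, IntegerVector dim, double sigma,
                           double alpha, double beta, double c,
                           bool bright_on_dark) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long ntot = (long)nx * ny * nz;
  std::vector<double> in(vol.begin(), vol.end());
  std::vector<double> tmp(ntot), work(ntot);
  std::vector<double> hxx(ntot), hyy(ntot), hzz(ntot), hxy(ntot), hxz(ntot), hyz(ntot);
  smooth_deriv(in, hxx, tmp, nx, ny, nz, sigma, 2, 0, 0);
  smooth_deriv(in, hyy, tmp, nx, ny, nz, sigma, 0, 2, 0);
  smooth_deriv(in, hzz, tmp, nx, ny, nz, sigma, 0, 0, 2);
  smooth_deriv(in, hxy, tmp, nx, ny, nz, sigma, 1, 1, 0);
  smooth_deriv(in, hxz, tmp, nx, ny, nz, sigma, 1, 0, 1);
  smooth_deriv(in, hyz, tmp, nx, ny, nz, sigma, 0, 1, 1);
  double g = sigma * sigma;  // gamma-normalization, gamma = 2
  std::vector<double> l1(ntot), l2(ntot), l3(ntot);
  double maxS2 = 0.0;
  for (long v = 0; v < ntot; ++v) {
    double e1, e2, e3;
    eig3_sym(g * hxx[v], g * hxy[v], g * hxz[v], g * hyy[v], g * hyz[v], g * hzz[v],
             e1, e2, e3);
    l1[v] = e1; l2[v] = e2; l3[v] = e3;
    double s2 = e1 * e1 + e2 * e2 + e3 * e3;
    if (s2 > maxS2) maxS2 = s2;
  }
  double cc = (c > 0) ? c : 0.5 * std::sqrt(maxS2);
  if (cc <= 0) cc = 1.0;
  // structure floor: Hessian norms at rounding-noise level (relative to the
  // intensity scale) carry no geometry and are suppressed
  double iMax = 0.0;
  for (long v = 0; v < ntot; ++v)
    iMax = std::max(iMax, std::fabs(in[v]));
  double sEps = 1e-9 * (iMax + 1.0);
  NumericVector out(ntot);
  for (long v = 0; v < ntot; ++v) {
    double e1 = l1[v], e2 = l2[v], e3 = l3[v];
    if (std::sqrt(e1 * e1 + e2 * e2 + e3 * e3) < sEps) { out[v] = 0.0; continue; }
    bool suppress = bright_on_dark ? (e2 > 0 || e3 > 0) : (e2 < 0 || e3 < 0);
    if (suppress) { out[v] = 0.0; continue; }
    double a2 = std::fabs(e2), a3 = std::fabs(e3);
    if (a3 < 1e-300) { out[v] = 0.0; continue; }
    double RA = a2 / a3;
    double RB = std::fabs(e1) / std::sqrt(a2 * a3);
    double S2 = e1 * e1 + e2 * e2 + e3 * e3;
    double vv = (1.0 - std::exp(-RA * RA / (2.0 * alpha * alpha)))
              * std::exp(-RB * RB / (2.0 * beta * beta))
              * (1.0 - std::exp(-S2 / (2.0 * cc * cc)));
    out[v] = vv;
  }
  out.attr("dim") = dim;
  return out;
}

// Plain separable Gaussian smoothing (used for noise suppression and for the
// pre-isosurface indicator smoothing).
// [[Rcpp::export(name = ".gauss_smooth")]]
NumericVector gauss_smooth(NumericVector vol, IntegerVector dim, double sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long ntot = (long)nx * ny * nz;
  std::vector<double> in(vol.begin(), vol.end()), out(ntot), tmp(ntot);
  smooth_deriv(in, out, tmp, nx, ny, nz, sigma, 0, 0, 0);
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = dim;
  return res;
}
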