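#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// 2D TOF projector for a single-ring geometry.
//
// Conventions shared with the R side:
//  - image: nx * ny voxels, column index = ix + iy*nx (0-based), voxel (ix,iy)
//    center at (x0 + (ix+0.5)*sp, y0 + (iy+0.5)*sp) with x0 = -nx*sp/2.
//  - a LOR is the chord between two crystal centers a -> b (a,b 0-based ids);
//    signed TOF coordinate s is measured from the chord midpoint, positive
//    toward crystal b (the higher crystal id).
//  - flat sinogram bin = lor * n_tof + k, k = 0..n_tof-1, bin (n_tof-1)/2
//    centered at s = 0; bin centers spaced by s_bin (mm).
//  - TOF kernel: Gaussian (sd sigma_s, mm) integrated over each bin.

struct Trace {
  std::vector<int> vox;
  std::vector<double> len;
  std::vector<double> s;
};

static void trace_chord(double ax, double ay, double bx, double by,
                        int nx, int ny, double sp, Trace &tr) {
  tr.vox.clear(); tr.len.clear(); tr.s.clear();
  const double dx = bx - ax, dy = by - ay;
  const double L = std::sqrt(dx * dx + dy * dy);
  if (L <= 0.0) return;
  const double x0 = -0.5 * nx * sp, y0 = -0.5 * ny * sp;
  double amin = 0.0, amax = 1.0;
  if (std::fabs(dx) < 1e-12) {
    if (ax <= x0 || ax >= x0 + nx * sp) return;
  } else {
    double a1 = (x0 - ax) / dx, a2 = (x0 + nx * sp - ax) / dx;
    amin = std::max(amin, std::min(a1, a2));
    amax = std::min(amax, std::max(a1, a2));
  }
  if (std::fabs(dy) < 1e-12) {
    if (ay <= y0 || ay >= y0 + ny * sp) return;
  } else {
    double a1 = (y0 - ay) / dy, a2 = (y0 + ny * sp - ay) / dy;
    amin = std::max(amin, std::min(a1, a2));
    amax = std::min(amax, std::max(a1, a2));
  }
  if (amin >= amax) return;
  std::vector<double> al;
  al.reserve(nx + ny + 4);
  al.push_back(amin);
  al.push_back(amax);
  if (std::fabs(dx) > 1e-12)
    for (int i = 0; i <= nx; ++i) {
      double a = (x0 + i * sp - ax) / dx;
      if (a > amin + 1e-12 && a < amax - 1e-12) al.push_back(a);
    }
  if (std::fabs(dy) > 1e-12)
    for (int i = 0; i <= ny; ++i) {
      double a = (y0 + i * sp - ay) / dy;
      if (a > amin + 1e-12 && a < amax - 1e-12) al.push_back(a);
    }
  std::sort(al.begin(), al.end());
  for (size_t t = 0; t + 1 < al.size(); ++t) {
    double a0 = al[t], a1 = al[t + 1];
    if (a1 - a0 < 1e-12) continue;
    double am = 0.5 * (a0 + a1);
    double xm = ax + am * dx, ym = ay + am * dy;
    int ix = (int)std::floor((xm - x0) / sp);
    int iy = (int)std::floor((ym - y0) / sp);
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) continue;
    tr.vox.push_back(ix + iy * nx);
    tr.len.push_back((a1 - a0) * L);
    tr.s.push_back(am * L - 0.5 * L);
  }
}

static inline double norm_cdf(double x) {
  return 0.5 * std::erfc(-x * M_SQRT1_2);
}

// kernel factor of TOF bin k (0-based) for a point at signed position s
static inline double tof_factor(double s, int k, int n_tof, double s_bin,
                                double sigma_s) {
  const double sc = (k - (n_tof - 1) / 2.0) * s_bin;
  if (sigma_s <= 0.0) {
    // degenerate kernel: indicator of the bin
    return (s >= sc - 0.5 * s_bin && s < sc + 0.5 * s_bin) ? 1.0 : 0.0;
  }
  return norm_cdf((sc + 0.5 * s_bin - s) / sigma_s) -
         norm_cdf((sc - 0.5 * s_bin - s) / sigma_s);
}

// [[Rcpp::export]]
List cpp_trace(double ax, double ay, double bx, double by,
               int nx, int ny, double spacing) {
  Trace tr;
  trace_chord(ax, ay, bx, by, nx, ny, spacing, tr);
  return List::create(_["vox"] = wrap(tr.vox), _["len"] = wrap(tr.len),
                      _["s"] = wrap(tr.s));
}

// [[Rcpp::export]]
NumericVector cpp_forward(NumericVector x, int nx, int ny, double spacing,
                          NumericVector crx, NumericVector cry,
                          IntegerVector lor_a, IntegerVector lor_b,
                          IntegerVector active, int n_tof, double s_bin,
                          double sigma_s) {
  const int n_lor = lor_a.size();
  NumericVector out(n_lor * n_tof);
  Trace tr;
  const double cut = (sigma_s > 0.0) ? 6.0 * sigma_s + 0.5 * s_bin : 0.5 * s_bin + 1e-9;
  for (int u = 0; u < active.size(); ++u) {
    const int l = active[u];
    const int a = lor_a[l], b = lor_b[l];
    trace_chord(crx[a], cry[a], crx[b], cry[b], nx, ny, spacing, tr);
    const int nv = tr.vox.size();
    if (nv == 0) continue;
    for (int k = 0; k < n_tof; ++k) {
      const double sc = (k - (n_tof - 1) / 2.0) * s_bin;
      double acc = 0.0;
      for (int v = 0; v < nv; ++v) {
        const double xv = x[tr.vox[v]];
        if (xv == 0.0) continue;
        if (std::fabs(tr.s[v] - sc) > cut) continue;
        acc += xv * tr.len[v] * tof_factor(tr.s[v], k, n_tof, s_bin, sigma_s);
      }
      out[(R_xlen_t)l * n_tof + k] = acc;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_backward(NumericVector sino, int nx, int ny, double spacing,
                           NumericVector crx, NumericVector cry,
                           IntegerVector lor_a, IntegerVector lor_b,
                           IntegerVector active, int n_tof, double s_bin,
                           double sigma_s) {
  NumericVector img(nx * ny);
  Trace tr;
  const double cut = (sigma_s > 0.0) ? 6.0 * sigma_s + 0.5 * s_bin : 0.5 * s_bin + 1e-9;
  for (int u = 0; u < active.size(); ++u) {
    const int l = active[u];
    const int a = lor_a[l], b = lor_b[l];
    trace_chord(crx[a], cry[a], crx[b], cry[b], nx, ny, spacing, tr);
    const int nv = tr.vox.size();
    if (nv == 0) continue;
    for (int k = 0; k < n_tof; ++k) {
      const double d = sino[(R_xlen_t)l * n_tof + k];
      if (d == 0.0) continue;
      const double sc = (k - (n_tof - 1) / 2.0) * s_bin;
      for (int v = 0; v < nv; ++v) {
        if (std::fabs(tr.s[v] - sc) > cut) continue;
        img[tr.vox[v]] += d * tr.len[v] * tof_factor(tr.s[v], k, n_tof, s_bin, sigma_s);
      }
    }
  }
  return img;
}

// sensitivity image: backprojection of ones over the given LORs (all TOF bins)
// [[Rcpp::export]]
NumericVector cpp_sensitivity(int nx, int ny, double spacing,
                              NumericVector crx, NumericVector cry,
                              IntegerVector lor_a, IntegerVector lor_b,
                              IntegerVector active, int n_tof, double s_bin,
                              double sigma_s) {
  NumericVector img(nx * ny);
  Trace tr;
  for (int u = 0; u < active.size(); ++u) {
    const int l = active[u];
    trace_chord(crx[lor_a[l]], cry[lor_a[l]], crx[lor_b[l]], cry[lor_b[l]],
                nx, ny, spacing, tr);
    const int nv = tr.vox.size();
    for (int v = 0; v < nv; ++v) {
      double tot = 0.0;
      for (int k = 0; k < n_tof; ++k)
        tot += tof_factor(tr.s[v], k, n_tof, s_bin, sigma_s);
      img[tr.vox[v]] += tr.len[v] * tot;
    }
  }
  return img;
}
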