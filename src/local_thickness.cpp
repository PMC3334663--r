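#include <Rcpp.h>
#include <vector>
#include <array>
#include <queue>
#include <cmath>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform of a sampled function f (Felzenszwalb &
// Huttenlocher 2012). d[q] = min_p (q - p)^2 + f[p].
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF) { v[0] = q; z[1] = INF; continue; }
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance transform of a 3D logical array.
// Foreground (true) voxels get the squared distance, in voxel units, to the
// nearest background voxel centre. If pad_background, the volume is
// conceptually surrounded by one layer of background (open border);
// otherwise the border acts as a hard wall.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims,
                         bool pad_background) {
  const int nx0 = dims[0], ny0 = dims[1], nz0 = dims[2];
  const int pad = pad_background ? 1 : 0;
  const int nx = nx0 + 2 * pad, ny = ny0 + 2 * pad, nz = nz0 + 2 * pad;
  const size_t N = (size_t)nx * ny * nz;

  std::vector<double> g(N, 0.0);
  for (int z = 0; z < nz0; z++)
    for (int y = 0; y < ny0; y++)
      for (int x = 0; x < nx0; x++) {
        size_t src = (size_t)x + (size_t)nx0 * (y + (size_t)ny0 * z);
        size_t dst = (size_t)(x + pad) +
                     (size_t)nx * ((y + pad) + (size_t)ny * (z + pad));
        g[dst] = mask[src] ? INF : 0.0;
      }

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++) {
      size_t base = (size_t)nx * (y + (size_t)ny * z);
      bool any = false;
      for (int x = 0; x < nx; x++) { f[x] = g[base + x]; if (f[x] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, nx, v, zbuf);
      for (int x = 0; x < nx; x++) g[base + x] = d[x];
    }
  // pass along y
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++) {
      size_t base = (size_t)x + (size_t)nx * ny * (size_t)z;
      bool any = false;
      for (int y = 0; y < ny; y++) { f[y] = g[base + (size_t)nx * y]; if (f[y] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, ny, v, zbuf);
      for (int y = 0; y < ny; y++) g[base + (size_t)nx * y] = d[y];
    }
  // pass along z
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      size_t base = (size_t)x + (size_t)nx * y;
      bool any = false;
      for (int z = 0; z < nz; z++) { f[z] = g[base + (size_t)nx * ny * z]; if (f[z] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, nz, v, zbuf);
      for (int z = 0; z < nz; z++) g[base + (size_t)nx * ny * z] = d[z];
    }

  NumericVector out((R_xlen_t)nx0 * ny0 * nz0);
  for (int z = 0; z < nz0; z++)
    for (int y = 0; y < ny0; y++)
      for (int x = 0; x < nx0; x++) {
        size_t src = (size_t)(x + pad) +
                     (size_t)nx * ((y + pad) + (size_t)ny * (z + pad));
        size_t dst = (size_t)x + (size_t)nx0 * (y + (size_t)ny0 * z);
        out[dst] = g[src];
      }
  out.attr("dim") = dims;
  return out;
}

// Maximal-sphere local thickness (direct 3D method). For every domain voxel
// the value is the diameter, in voxel units, of the largest sphere fully
// contained in the domain that covers the voxel: distance transform ->
// distance-ridge pruning -> sphere propagation. Non-domain voxels get NA.
// [[Rcpp::export]]
NumericVector local_thickness_cpp(LogicalVector mask, IntegerVector dims,
                                  bool pad_background) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t N = (size_t)nx * ny * nz;
  NumericVector r2v = edt_sq_cpp(mask, dims, pad_background);
  const double* r2 = REAL(r2v);

  // Distance ridge: voxel p is redundant when some 26-neighbour q satisfies
  // sqrt(r2[q]) >= sqrt(r2[p]) + |p - q| (its ball contains p's ball).
  std::vector<size_t> centers;
  centers.reserve(N / 8);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        size_t i = (size_t)x + (size_t)nx * (y + (size_t)ny * z);
        if (!mask[i] || r2[i] <= 0) continue;
        double rp = std::sqrt(r2[i]);
        bool redundant = false;
        for (int dz = -1; dz <= 1 && !redundant; dz++)
          for (int dy = -1; dy <= 1 && !redundant; dy++)
            for (int dx = -1; dx <= 1; dx++) {
              if (!dx && !dy && !dz) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
                continue;
              size_t j = (size_t)xx + (size_t)nx * (yy + (size_t)ny * zz);
              if (!mask[j]) continue;
              double dist = std::sqrt((double)(dx * dx + dy * dy + dz * dz));
              if (std::sqrt(r2[j]) >= rp + dist - 1e-9) { redundant = true; break; }
            }
        if (!redundant) centers.push_back(i);
      }

  // Largest spheres first so most voxels are written once.
  std::sort(centers.begin(), centers.end(),
            [&](size_t a, size_t b) { return r2[a] > r2[b]; });

  std::vector<double> th(N, 0.0);
  for (size_t c : centers) {
    double rr2 = r2[c];
    if (rr2 <= 0) continue;
    int x0 = (int)(c % nx);
    int y0 = (int)((c / nx) % ny);
    int z0 = (int)(c / ((size_t)nx * ny));
    int r = (int)std::floor(std::sqrt(rr2) + 1e-9);
    int zlo = std::max(0, z0 - r), zhi = std::min(nz - 1, z0 + r);
    for (int z = zlo; z <= zhi; z++) {
      double dz2 = (double)(z - z0) * (z - z0);
      int ylo = std::max(0, y0 - r), yhi = std::min(ny - 1, y0 + r);
      for (int y = ylo; y <= yhi; y++) {
        double dyz2 = dz2 + (double)(y - y0) * (y - y0);
        if (dyz2 > rr2) continue;
        int xr = (int)std::floor(std::sqrt(rr2 - dyz2) + 1e-9);
        int xlo = std::max(0, x0 - xr), xhi = std::min(nx - 1, x0 + xr);
        size_t base = (size_t)nx * (y + (size_t)ny * z);
        for (int x = xlo; x <= xhi; x++) {
          size_t i = base + x;
          if (mask[i] && th[i] < rr2) th[i] = rr2;
        }
      }
    }
  }

  NumericVector out(N);
  for (size_t i = 0; i < N; i++)
    out[i] = mask[i] ? 2.0 * std::sqrt(th[i]) : NA_REAL;
  out.attr("dim") = dims;
  return out;
}

// Connected-component labelling of a 3D logical array with 6- or
// 26-connectivity. Background voxels get label 0.
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t N = (size_t)nx * ny * nz;
  IntegerVector labels(N, 0);
  labels.attr("dim") = dims;

  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (!dx && !dy && !dz) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m != 1) continue;
        offs.push_back({dx, dy, dz});
      }

  int lab = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < N; s++) {
    if (!mask[s] || labels[s]) continue;
    lab++;
    labels[s] = lab;
    stack.push_back(s);
    while (!stack.empty()) {
      size_t i = stack.back();
      stack.pop_back();
      int x = (int)(i % nx), y = (int)((i / nx) % ny),
          z = (int)(i / ((size_t)nx * ny));
      for (auto& o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        size_t j = (size_t)xx + (size_t)nx * (yy + (size_t)ny * zz);
        if (mask[j] && !labels[j]) { labels[j] = lab; stack.push_back(j); }
      }
    }
  }
  return labels;
}
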