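#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Voxel grids are stored as flat vectors in column-major (x fastest) order:
// index = ix + nx*(iy + ny*iz), 0-based.

static inline int vidx(int ix, int iy, int iz, int nx, int ny) {
  return ix + nx * (iy + (size_t)ny * iz);
}

// Clearance field: for each voxel center, min over atoms of
// (distance to atom center - atom vdW radius), capped above at `cap`.
// Values above cap are reported as cap; only thresholds below cap are
// meaningful downstream, which lets each atom update a local neighborhood
// only.
// [[Rcpp::export(name = ".grid_clearance")]]
NumericVector grid_clearance(NumericVector origin, IntegerVector dims,
                             double spacing, NumericMatrix coords,
                             NumericVector radii, double cap) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const size_t nvox = (size_t)nx * ny * nz;
  NumericVector out(nvox, cap);
  const int natom = coords.nrow();
  for (int a = 0; a < natom; ++a) {
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    const double r = radii[a];
    const double reach = r + cap; // beyond this the atom cannot beat cap
    int ix0 = (int)std::floor((ax - reach - ox) / spacing);
    int ix1 = (int)std::ceil((ax + reach - ox) / spacing);
    int iy0 = (int)std::floor((ay - reach - oy) / spacing);
    int iy1 = (int)std::ceil((ay + reach - oy) / spacing);
    int iz0 = (int)std::floor((az - reach - oz) / spacing);
    int iz1 = (int)std::ceil((az + reach - oz) / spacing);
    if (ix0 < 0) ix0 = 0; if (iy0 < 0) iy0 = 0; if (iz0 < 0) iz0 = 0;
    if (ix1 >= nx) ix1 = nx - 1;
    if (iy1 >= ny) iy1 = ny - 1;
    if (iz1 >= nz) iz1 = nz - 1;
    for (int iz = iz0; iz <= iz1; ++iz) {
      const double dz = oz + iz * spacing - az;
      for (int iy = iy0; iy <= iy1; ++iy) {
        const double dy = oy + iy * spacing - ay;
        const double dyz2 = dy * dy + dz * dz;
        for (int ix = ix0; ix <= ix1; ++ix) {
          const double dx = ox + ix * spacing - ax;
          const double c = std::sqrt(dx * dx + dyz2) - r;
          const int id = vidx(ix, iy, iz, nx, ny);
          if (c < out[id]) out[id] = c;
        }
      }
    }
  }
  return out;
}

// 6-connected BFS over `open` voxels, from the given 0-based seed indices.
// Returns a logical mask of reached voxels (seeds must be open to count).
// [[Rcpp::export(name = ".grid_flood")]]
LogicalVector grid_flood(LogicalVector open, IntegerVector dims,
                         IntegerVector seeds) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nvox = (size_t)nx * ny * nz;
  std::vector<char> seen(nvox, 0);
  std::queue<int> q;
  for (int s = 0; s < seeds.size(); ++s) {
    int id = seeds[s];
    if (id >= 0 && (size_t)id < nvox && open[id] && !seen[id]) {
      seen[id] = 1;
      q.push(id);
    }
  }
  while (!q.empty()) {
    int id = q.front(); q.pop();
    int iz = id / (nx * ny);
    int rem = id - iz * nx * ny;
    int iy = rem / nx;
    int ix = rem - iy * nx;
    const int nbx[6] = {ix - 1, ix + 1, ix, ix, ix, ix};
    const int nby[6] = {iy, iy, iy - 1, iy + 1, iy, iy};
    const int nbz[6] = {iz, iz, iz, iz, iz - 1, iz + 1};
    for (int k = 0; k < 6; ++k) {
      if (nbx[k] < 0 || nbx[k] >= nx || nby[k] < 0 || nby[k] >= ny ||
          nbz[k] < 0 || nbz[k] >= nz)
        continue;
      int nid = vidx(nbx[k], nby[k], nbz[k], nx, ny);
      if (open[nid] && !seen[nid]) {
        seen[nid] = 1;
        q.push(nid);
      }
    }
  }
  LogicalVector out(nvox);
  for (size_t i = 0; i < nvox; ++i) out[i] = seen[i] != 0;
  return out;
}

// 6-connected component labelling of `mask`; labels 1..k, 0 elsewhere.
// [[Rcpp::export(name = ".grid_components")]]
IntegerVector grid_components(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nvox = (size_t)nx * ny * nz;
  IntegerVector lab(nvox, 0);
  int next = 0;
  std::queue<int> q;
  for (size_t start = 0; start < nvox; ++start) {
    if (!mask[start] || lab[start]) continue;
    ++next;
    lab[start] = next;
    q.push((int)start);
    while (!q.empty()) {
      int id = q.front(); q.pop();
      int iz = id / (nx * ny);
      int rem = id - iz * nx * ny;
      int iy = rem / nx;
      int ix = rem - iy * nx;
      const int nbx[6] = {ix - 1, ix + 1, ix, ix, ix, ix};
      const int nby[6] = {iy, iy, iy - 1, iy + 1, iy, iy};
      const int nbz[6] = {iz, iz, iz, iz, iz - 1, iz + 1};
      for (int k = 0; k < 6; ++k) {
        if (nbx[k] < 0 || nbx[k] >= nx || nby[k] < 0 || nby[k] >= ny ||
            nbz[k] < 0 || nbz[k] >= nz)
          continue;
        int nid = vidx(nbx[k], nby[k], nbz[k], nx, ny);
        if (mask[nid] && !lab[nid]) {
          lab[nid] = next;
          q.push(nid);
        }
      }
    }
  }
  return lab;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher), helper.
static void edt1d(std::vector<double> &f, std::vector<double> &d,
                  std::vector<int> &v, std::vector<double> &z, int n) {
  const double INF = std::numeric_limits<double>::infinity();
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

// Exact Euclidean distance (in voxel units) from every voxel to the nearest
// TRUE voxel of `mask`, via separable squared distance transform.
// [[Rcpp::export(name = ".grid_edt")]]
NumericVector grid_edt(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nvox = (size_t)nx * ny * nz;
  // large finite sentinel instead of infinity: keeps the parabola
  // intersection finite on scanlines with no mask voxel
  const double FAR = 1e12;
  std::vector<double> g(nvox);
  for (size_t i = 0; i < nvox; ++i) g[i] = mask[i] ? 0.0 : FAR;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // pass along x
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy) {
      for (int ix = 0; ix < nx; ++ix) f[ix] = g[vidx(ix, iy, iz, nx, ny)];
      edt1d(f, d, v, z, nx);
      for (int ix = 0; ix < nx; ++ix) g[vidx(ix, iy, iz, nx, ny)] = d[ix];
    }
  // pass along y
  for (int iz = 0; iz < nz; ++iz)
    for (int ix = 0; ix < nx; ++ix) {
      for (int iy = 0; iy < ny; ++iy) f[iy] = g[vidx(ix, iy, iz, nx, ny)];
      edt1d(f, d, v, z, ny);
      for (int iy = 0; iy < ny; ++iy) g[vidx(ix, iy, iz, nx, ny)] = d[iy];
    }
  // pass along z
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      for (int iz = 0; iz < nz; ++iz) f[iz] = g[vidx(ix, iy, iz, nx, ny)];
      edt1d(f, d, v, z, nz);
      for (int iz = 0; iz < nz; ++iz) g[vidx(ix, iy, iz, nx, ny)] = d[iz];
    }
  NumericVector out(nvox);
  for (size_t i = 0; i < nvox; ++i) out[i] = std::sqrt(g[i]);
  return out;
}

// Shrake-Rupley exposure: for each atom, count of its sphere points (rows of
// `pts`, unit sphere) that fall outside every other atom's expanded sphere.
// [[Rcpp::export(name = ".sr_exposed")]]
IntegerVector sr_exposed(NumericMatrix coords, NumericVector radii,
                         double probe, NumericMatrix pts) {
  const int n = coords.nrow(), npts = pts.nrow();
  IntegerVector out(n);
  std::vector<double> er(n);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) {
    er[i] = radii[i] + probe;
    if (er[i] > rmax) rmax = er[i];
  }
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    const double cut = er[i] + rmax;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi,
             dz = coords(j, 2) - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      double lim = er[i] + er[j];
      if (d2 < lim * lim && d2 < cut * cut) nb.push_back(j);
    }
    int exposed = 0;
    for (int p = 0; p < npts; ++p) {
      const double px = xi + er[i] * pts(p, 0);
      const double py = yi + er[i] * pts(p, 1);
      const double pz = zi + er[i] * pts(p, 2);
      bool out_all = true;
      for (size_t k = 0; k < nb.size(); ++k) {
        int j = nb[k];
        double dx = px - coords(j, 0), dy = py - coords(j, 1),
               dz = pz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < er[j] * er[j]) {
          out_all = false;
          break;
        }
      }
      if (out_all) ++exposed;
    }
    out[i] = exposed;
  }
  return out;
}
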