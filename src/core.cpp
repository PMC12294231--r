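// Low-level 3D voxel primitives used by the descriptor engine.
// Arrays arrive as R vectors in column-major order with dim = (nz, ny, nx);
// the first index varies fastest. All distances are physical (per-axis
// spacing in micrometres).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
#include <array>
#include <cstdint>

using namespace Rcpp;

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// ---------------------------------------------------------------------------
// Connected-component labeling (6- or 26-connectivity), BFS flood fill.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);

  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dz, dy, dx});
      }

  int next = 0;
  std::vector<int> stack;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = idx3(z, y, x, nz, ny);
        if (!mask[i] || lab[i]) continue;
        ++next;
        lab[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          int cur = stack.back();
          stack.pop_back();
          int cz = cur % nz, rem = cur / nz;
          int cy = rem % ny, cx = rem / ny;
          for (const auto &o : offs) {
            int zz = cz + o[0], yy = cy + o[1], xx = cx + o[2];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            int j = idx3(zz, yy, xx, nz, ny);
            if (mask[j] && !lab[j]) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
  lab.attr("dim") = dim;
  return lab;
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable over axes, anisotropic spacing supported.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double> &f, std::vector<double> &d, int n, double h) {
  // lower envelope of parabolas f[i] + (h*(q-i))^2; infinite f[i] are absent
  const double inf = std::numeric_limits<double>::infinity();
  int q0 = 0;
  while (q0 < n && !std::isfinite(f[q0])) ++q0;
  if (q0 == n) {
    for (int q = 0; q < n; ++q) d[q] = inf;
    return;
  }
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = q0;
  zb[0] = -inf;
  zb[1] = inf;
  const double h2 = h * h;
  for (int q = q0 + 1; q < n; ++q) {
    if (!std::isfinite(f[q])) continue;
    double s = 0.0;
    while (true) {
      int p = v[k];
      s = ((f[q] + h2 * (double)q * q) - (f[p] + h2 * (double)p * p)) /
          (2.0 * h2 * (q - p));
      if (s <= zb[k] && k > 0) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = inf;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[j + 1] < q) ++j;
    int p = v[j];
    double dq = h * (q - p);
    d[q] = dq * dq + f[p];
  }
}

// Distance (um) from every voxel to the nearest zero (background) voxel of
// `fg`; foreground voxels with no background anywhere get Inf.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector fg, IntegerVector dim, NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  const double inf = std::numeric_limits<double>::infinity();
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fg[i] ? inf : 0.0;

  std::vector<double> f, d;
  // pass along z (fastest axis)
  f.resize(nz); d.resize(nz);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = out[idx3(z, y, x, nz, ny)];
      dt1d(f, d, nz, spacing[0]);
      for (int z = 0; z < nz; ++z) out[idx3(z, y, x, nz, ny)] = d[z];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = out[idx3(z, y, x, nz, ny)];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[idx3(z, y, x, nz, ny)] = d[y];
    }
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) f[x] = out[idx3(z, y, x, nz, ny)];
      dt1d(f, d, nx, spacing[2]);
      for (int x = 0; x < nx; ++x) out[idx3(z, y, x, nz, ny)] = d[x];
    }
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Geodesic diameter of a single connected mask, two-sweep Dijkstra on the
// 26-neighborhood graph with physical edge lengths. The two-sweep scheme
// (farthest point from an arbitrary start, then farthest from that) is the
// standard fast approximation and is exact for convex bodies.
// ---------------------------------------------------------------------------

static std::vector<double> dijkstra_mask(const LogicalVector &mask, int nz, int ny,
                                         int nx, const NumericVector &spacing,
                                         int start, int &farthest) {
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> dist(n, std::numeric_limits<double>::infinity());
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  dist[start] = 0.0;
  pq.push({0.0, start});

  // 5x5x5 visible-displacement moves (coprime offsets): chamfer metric error
  // ~1-2 % versus ~8 % for the plain 26-neighborhood
  std::vector<std::array<int, 3>> offs;
  std::vector<double> w;
  auto gcd3 = [](int a, int b, int c) {
    auto g = [](int x, int y) { while (y) { int t = x % y; x = y; y = t; } return x; };
    return g(g(std::abs(a), std::abs(b)), std::abs(c));
  };
  for (int dz = -2; dz <= 2; ++dz)
    for (int dy = -2; dy <= 2; ++dy)
      for (int dx = -2; dx <= 2; ++dx) {
        if (!dz && !dy && !dx) continue;
        if (gcd3(dz, dy, dx) != 1) continue;
        offs.push_back({dz, dy, dx});
        double a = dz * spacing[0], b = dy * spacing[1], c = dx * spacing[2];
        w.push_back(std::sqrt(a * a + b * b + c * c));
      }

  farthest = start;
  double dmax = 0.0;
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double du = top.first; int u = top.second;
    if (du > dist[u]) continue;
    if (du > dmax) { dmax = du; farthest = u; }
    int cz = u % nz, rem = u / nz;
    int cy = rem % ny, cx = rem / ny;
    for (size_t k = 0; k < offs.size(); ++k) {
      int dz = offs[k][0], dy = offs[k][1], dx = offs[k][2];
      int zz = cz + dz, yy = cy + dy, xx = cx + dx;
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      int v = idx3(zz, yy, xx, nz, ny);
      if (!mask[v]) continue;
      if (std::abs(dz) == 2 || std::abs(dy) == 2 || std::abs(dx) == 2) {
        // long moves must not tunnel through background: one of the two
        // half-way voxels (floor/ceil of the midpoint) must be inside
        int fz = cz + (dz >= 0 ? dz / 2 : -((-dz) / 2));
        int fy = cy + (dy >= 0 ? dy / 2 : -((-dy) / 2));
        int fx = cx + (dx >= 0 ? dx / 2 : -((-dx) / 2));
        int gz2 = cz + dz - (dz >= 0 ? dz / 2 : -((-dz) / 2));
        int gy2 = cy + dy - (dy >= 0 ? dy / 2 : -((-dy) / 2));
        int gx2 = cx + dx - (dx >= 0 ? dx / 2 : -((-dx) / 2));
        bool okA = mask[idx3(fz, fy, fx, nz, ny)];
        bool okB = mask[idx3(gz2, gy2, gx2, nz, ny)];
        if (!okA && !okB) continue;
      }
      double alt = du + w[k];
      if (alt < dist[v]) {
        dist[v] = alt;
        pq.push({alt, v});
      }
    }
  }
  return dist;
}

// [[Rcpp::export(name = ".geodesic_diameter3d")]]
double geodesic_diameter3d(LogicalVector mask, IntegerVector dim,
                           NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  int start = -1;
  for (R_xlen_t i = 0; i < n; ++i)
    if (mask[i]) { start = (int)i; break; }
  if (start < 0) return NA_REAL;
  int far1 = start, far2 = start;
  dijkstra_mask(mask, nz, ny, nx, spacing, start, far1);
  std::vector<double> d2 = dijkstra_mask(mask, nz, ny, nx, spacing, far1, far2);
  return d2[far2];
}

// ---------------------------------------------------------------------------
// Convex-hull volume of a 3D point cloud, incremental hull. Only the volume
// is needed (convexity = body volume / hull volume), so coplanar extensions
// that do not change the volume may be skipped.
// ---------------------------------------------------------------------------

struct Facet {
  int a, b, c;
  double nxx, nyy, nzz, off; // outward normal, plane offset
  bool alive;
};

static inline void facet_plane(Facet &f, const std::vector<double> &px,
                               const std::vector<double> &py,
                               const std::vector<double> &pz) {
  double ux = px[f.b] - px[f.a], uy = py[f.b] - py[f.a], uz = pz[f.b] - pz[f.a];
  double vx = px[f.c] - px[f.a], vy = py[f.c] - py[f.a], vz = pz[f.c] - pz[f.a];
  f.nxx = uy * vz - uz * vy;
  f.nyy = uz * vx - ux * vz;
  f.nzz = ux * vy - uy * vx;
  f.off = f.nxx * px[f.a] + f.nyy * py[f.a] + f.nzz * pz[f.a];
}

// [[Rcpp::export(name = ".hull_volume3d")]]
double hull_volume3d(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) return 0.0;
  std::vector<double> px(n), py(n), pz(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    px[i] = pts(i, 0); py[i] = pts(i, 1); pz[i] = pts(i, 2);
    scale = std::max(scale, std::max(std::fabs(px[i]),
            std::max(std::fabs(py[i]), std::fabs(pz[i]))));
  }
  if (scale <= 0) scale = 1.0;
  const double eps = 1e-9 * scale * scale * scale;

  // initial tetrahedron: extremes in x, then farthest from segment, then plane
  int i0 = 0, i1 = 0;
  for (int i = 1; i < n; ++i) {
    if (px[i] < px[i0]) i0 = i;
    if (px[i] > px[i1]) i1 = i;
  }
  if (i0 == i1) i1 = (i0 + 1) % n;
  int i2 = -1; double best = -1.0;
  double ex = px[i1] - px[i0], ey = py[i1] - py[i0], ez = pz[i1] - pz[i0];
  for (int i = 0; i < n; ++i) {
    double wx = px[i] - px[i0], wy = py[i] - py[i0], wz = pz[i] - pz[i0];
    double cx = ey * wz - ez * wy, cy = ez * wx - ex * wz, cz = ex * wy - ey * wx;
    double a2 = cx * cx + cy * cy + cz * cz;
    if (a2 > best) { best = a2; i2 = i; }
  }
  if (best <= 0) return 0.0; // collinear
  int i3 = -1; best = 0.0;
  Facet base{i0, i1, i2, 0, 0, 0, 0, true};
  facet_plane(base, px, py, pz);
  for (int i = 0; i < n; ++i) {
    double d = base.nxx * px[i] + base.nyy * py[i] + base.nzz * pz[i] - base.off;
    if (std::fabs(d) > std::fabs(best)) { best = d; i3 = i; }
  }
  if (i3 < 0 || std::fabs(best) <= eps) return 0.0; // coplanar cloud

  std::vector<Facet> facets;
  auto add_facet = [&](int a, int b, int c, double cx0, double cy0, double cz0) {
    Facet f{a, b, c, 0, 0, 0, 0, true};
    facet_plane(f, px, py, pz);
    // orient outward w.r.t. interior point
    if (f.nxx * cx0 + f.nyy * cy0 + f.nzz * cz0 - f.off > 0) {
      std::swap(f.b, f.c);
      facet_plane(f, px, py, pz);
    }
    facets.push_back(f);
  };
  double cx0 = (px[i0] + px[i1] + px[i2] + px[i3]) / 4.0;
  double cy0 = (py[i0] + py[i1] + py[i2] + py[i3]) / 4.0;
  double cz0 = (pz[i0] + pz[i1] + pz[i2] + pz[i3]) / 4.0;
  add_facet(i0, i1, i2, cx0, cy0, cz0);
  add_facet(i0, i1, i3, cx0, cy0, cz0);
  add_facet(i0, i2, i3, cx0, cy0, cz0);
  add_facet(i1, i2, i3, cx0, cy0, cz0);

  std::vector<char> used(n, 0);
  used[i0] = used[i1] = used[i2] = used[i3] = 1;

  for (int i = 0; i < n; ++i) {
    if (used[i]) continue;
    // facets visible from point i
    std::vector<int> vis;
    for (size_t k = 0; k < facets.size(); ++k) {
      if (!facets[k].alive) continue;
      double d = facets[k].nxx * px[i] + facets[k].nyy * py[i] +
                 facets[k].nzz * pz[i] - facets[k].off;
      if (d > eps) vis.push_back((int)k);
    }
    if (vis.empty()) continue;
    // horizon: directed edges of visible facets whose reverse is absent
    std::vector<std::pair<int, int>> edges;
    for (int k : vis) {
      const Facet &f = facets[k];
      edges.push_back({f.a, f.b});
      edges.push_back({f.b, f.c});
      edges.push_back({f.c, f.a});
      facets[k].alive = false;
    }
    std::vector<std::pair<int, int>> horizon;
    for (const auto &e : edges) {
      bool twin = false;
      for (const auto &e2 : edges)
        if (e2.first == e.second && e2.second == e.first) { twin = true; break; }
      if (!twin) horizon.push_back(e);
    }
    for (const auto &e : horizon) add_facet(e.first, e.second, i, cx0, cy0, cz0);
  }

  double vol = 0.0;
  for (const auto &f : facets) {
    if (!f.alive) continue;
    double v = px[f.a] * (py[f.b] * pz[f.c] - pz[f.b] * py[f.c]) -
               py[f.a] * (px[f.b] * pz[f.c] - pz[f.b] * px[f.c]) +
               pz[f.a] * (px[f.b] * py[f.c] - py[f.b] * px[f.c]);
    vol += v;
  }
  return std::fabs(vol) / 6.0;
}
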