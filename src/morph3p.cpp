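// 3D image primitives used by the morphometry pipeline.
//
// All arrays arrive as R arrays with dim = c(nz, ny, nx), i.e. the z index is
// fastest-varying (column-major). Linear index of voxel (z, y, x) is
// z + nz * (y + ny * x). Physical spacing is (dz, dy, dx) along those axes,
// and distances are computed in physical units throughout.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// Euclidean distance transform (Felzenszwalb & Huttenlocher 2012), separable,
// with per-axis sample spacing so the result is exact on anisotropic grids.
// ---------------------------------------------------------------------------

// 1D squared-distance transform on samples at positions i*w, in place on f.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double w) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double qs = q * w, vs = v[k] * w;
      s = ((f[q] + qs * qs) - (f[v[k]] + vs * vs)) / (2.0 * qs - 2.0 * vs);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qs = q * w;
    while (z[k + 1] < qs) ++k;
    double diff = qs - v[k] * w;
    d[q] = diff * diff + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Distance from every voxel to the nearest zero voxel, physical units.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d_cpp(IntegerVector mask, IntegerVector dims,
                        double dz, double dy, double dx) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  // finite "infinity" keeps the parabola intersections well defined
  double big = nz * dz * nz * dz + ny * dy * ny * dy + nx * dx * nx * dx + 1.0;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? big : 0.0;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along z (stride 1)
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int q = 0; q < nz; ++q) f[q] = out[base + q];
      dt1d(f, d, v, z, nz, dz);
      for (int q = 0; q < nz; ++q) out[base + q] = f[q];
    }
  // pass along y (stride nz)
  for (int x = 0; x < nx; ++x)
    for (int zi = 0; zi < nz; ++zi) {
      R_xlen_t base = zi + (R_xlen_t)nz * ny * x;
      for (int q = 0; q < ny; ++q) f[q] = out[base + (R_xlen_t)nz * q];
      dt1d(f, d, v, z, ny, dy);
      for (int q = 0; q < ny; ++q) out[base + (R_xlen_t)nz * q] = f[q];
    }
  // pass along x (stride nz*ny)
  R_xlen_t sx = (R_xlen_t)nz * ny;
  for (int y = 0; y < ny; ++y)
    for (int zi = 0; zi < nz; ++zi) {
      R_xlen_t base = zi + (R_xlen_t)nz * y;
      for (int q = 0; q < nx; ++q) f[q] = out[base + sx * q];
      dt1d(f, d, v, z, nx, dx);
      for (int q = 0; q < nx; ++q) out[base + sx * q] = f[q];
    }

  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Topology-preserving 3D thinning to a curve skeleton.
//
// A border voxel may be deleted when it is a simple point for the (26, 6)
// adjacency pair (Malandain & Bertrand characterization: exactly one
// 26-connected foreground component in the punctured 26-neighborhood, and
// exactly one 6-connected background component in the 18-neighborhood that is
// 6-adjacent to the center) and is not a curve end point (exactly one
// foreground 26-neighbor). Deletion proceeds in six directional
// sub-iterations until stable, which keeps the result centered.
// ---------------------------------------------------------------------------

struct Off { int dz, dy, dx; };

static inline int cube_idx(int dz, int dy, int dx) {
  return (dz + 1) + 3 * ((dy + 1) + 3 * (dx + 1));
}

// foreground flags for the 3x3x3 cube around p; out-of-bounds = background
static void get_cube(const std::vector<unsigned char> &img,
                     int nz, int ny, int nx,
                     int z, int y, int x, unsigned char cube[27]) {
  for (int dxo = -1; dxo <= 1; ++dxo)
    for (int dyo = -1; dyo <= 1; ++dyo)
      for (int dzo = -1; dzo <= 1; ++dzo) {
        int zz = z + dzo, yy = y + dyo, xx = x + dxo;
        unsigned char val = 0;
        if (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 && xx < nx)
          val = img[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)];
        cube[cube_idx(dzo, dyo, dxo)] = val;
      }
}

static int count_fg_neighbors(const unsigned char cube[27]) {
  int c = 0;
  for (int i = 0; i < 27; ++i)
    if (i != cube_idx(0, 0, 0) && cube[i]) ++c;
  return c;
}

// number of 26-connected foreground components in the punctured neighborhood
static int fg_components26(const unsigned char cube[27]) {
  bool visited[27] = {false};
  int center = cube_idx(0, 0, 0);
  int ncomp = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == center || !cube[s] || visited[s]) continue;
    ++ncomp;
    std::vector<int> stack(1, s);
    visited[s] = true;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int cz = cur % 3 - 1, cy = (cur / 3) % 3 - 1, cx = cur / 9 - 1;
      for (int dz2 = -1; dz2 <= 1; ++dz2)
        for (int dy2 = -1; dy2 <= 1; ++dy2)
          for (int dx2 = -1; dx2 <= 1; ++dx2) {
            int z2 = cz + dz2, y2 = cy + dy2, x2 = cx + dx2;
            if (z2 < -1 || z2 > 1 || y2 < -1 || y2 > 1 || x2 < -1 || x2 > 1)
              continue;
            int idx = cube_idx(z2, y2, x2);
            if (idx == center || visited[idx] || !cube[idx]) continue;
            visited[idx] = true;
            stack.push_back(idx);
          }
    }
  }
  return ncomp;
}

// 6-connected background components within the 18-neighborhood that touch a
// 6-neighbor of the center
static int bg_components6(const unsigned char cube[27]) {
  int center = cube_idx(0, 0, 0);
  bool in18[27] = {false};
  for (int dz2 = -1; dz2 <= 1; ++dz2)
    for (int dy2 = -1; dy2 <= 1; ++dy2)
      for (int dx2 = -1; dx2 <= 1; ++dx2) {
        int l1 = std::abs(dz2) + std::abs(dy2) + std::abs(dx2);
        if (l1 >= 1 && l1 <= 2) in18[cube_idx(dz2, dy2, dx2)] = true;
      }
  bool visited[27] = {false};
  static const Off six[6] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  int ncomp = 0;
  for (int k = 0; k < 6; ++k) {
    int s = cube_idx(six[k].dz, six[k].dy, six[k].dx);
    if (cube[s] || visited[s]) continue;
    ++ncomp;
    std::vector<int> stack(1, s);
    visited[s] = true;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int cz = cur % 3 - 1, cy = (cur / 3) % 3 - 1, cx = cur / 9 - 1;
      for (int k2 = 0; k2 < 6; ++k2) {
        int z2 = cz + six[k2].dz, y2 = cy + six[k2].dy, x2 = cx + six[k2].dx;
        if (z2 < -1 || z2 > 1 || y2 < -1 || y2 > 1 || x2 < -1 || x2 > 1)
          continue;
        int idx = cube_idx(z2, y2, x2);
        if (!in18[idx] || idx == center || visited[idx] || cube[idx]) continue;
        visited[idx] = true;
        stack.push_back(idx);
      }
    }
  }
  return ncomp;
}

static bool is_simple(const unsigned char cube[27]) {
  return fg_components26(cube) == 1 && bg_components6(cube) == 1;
}

// [[Rcpp::export(name = ".thin3d")]]
IntegerVector thin3d_cpp(IntegerVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<unsigned char> img(n);
  for (R_xlen_t i = 0; i < n; ++i) img[i] = mask[i] ? 1 : 0;

  static const Off dirs[6] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  unsigned char cube[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      // candidates: foreground voxels whose d-neighbor is background AND that
      // are already simple non-end points at pass start -- prefiltering by
      // simplicity is what stops deletions from cascading through voxels
      // that only become simple mid-pass
      std::vector<R_xlen_t> cand;
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
          for (int z = 0; z < nz; ++z) {
            R_xlen_t i = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
            if (!img[i]) continue;
            int zz = z + dirs[d].dz, yy = y + dirs[d].dy, xx = x + dirs[d].dx;
            bool nb_bg = true;
            if (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 && xx < nx)
              nb_bg = !img[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)];
            if (!nb_bg) continue;
            // peel only true directional borders: the opposite neighbor must
            // be foreground. A voxel that is one-thick along d is a membrane
            // there, and deleting membranes in their thin direction is what
            // lets classical thinning eat flat structures end to end.
            int zo = z - dirs[d].dz, yo = y - dirs[d].dy, xo = x - dirs[d].dx;
            bool op_fg = false;
            if (zo >= 0 && zo < nz && yo >= 0 && yo < ny && xo >= 0 && xo < nx)
              op_fg = img[zo + (R_xlen_t)nz * (yo + (R_xlen_t)ny * xo)] != 0;
            if (!op_fg) continue;
            get_cube(img, nz, ny, nx, z, y, x, cube);
            if (count_fg_neighbors(cube) <= 1) continue;
            if (!is_simple(cube)) continue;
            cand.push_back(i);
          }
      // sequential re-checked deletion keeps topology exact
      for (R_xlen_t ci = 0; ci < (R_xlen_t)cand.size(); ++ci) {
        R_xlen_t i = cand[ci];
        if (!img[i]) continue;
        int z = (int)(i % nz);
        int y = (int)((i / nz) % ny);
        int x = (int)(i / ((R_xlen_t)nz * ny));
        get_cube(img, nz, ny, nx, z, y, x, cube);
        int nn = count_fg_neighbors(cube);
        if (nn <= 1) continue;           // end point or isolated: keep
        if (!is_simple(cube)) continue;
        img[i] = 0;
        changed = true;
      }
    }
  }

  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = img[i];
  return out;
}

// ---------------------------------------------------------------------------
// 3D connected-component labeling (BFS), connectivity 6 or 26.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d_cpp(IntegerVector mask, IntegerVector dims,
                          int connectivity) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector out(n);
  std::vector<Off> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int l1 = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && l1 != 1) continue;
        offs.push_back({dz, dy, dx});
      }
  int label = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || out[s]) continue;
    ++label;
    out[s] = label;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int z = (int)(cur % nz);
      int y = (int)((cur / nz) % ny);
      int x = (int)(cur / ((R_xlen_t)nz * ny));
      for (size_t k = 0; k < offs.size(); ++k) {
        int zz = z + offs[k].dz, yy = y + offs[k].dy, xx = x + offs[k].dx;
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (!mask[j] || out[j]) continue;
        out[j] = label;
        stack.push_back(j);
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 3D median filter over a (2r+1)^3 box clipped at the volume boundary.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".medianFilter3d")]]
NumericVector median3d_cpp(NumericVector img, IntegerVector dims,
                           int rz, int ry, int rx) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve((2 * rz + 1) * (2 * ry + 1) * (2 * rx + 1));
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        buf.clear();
        for (int xx = std::max(0, x - rx); xx <= std::min(nx - 1, x + rx); ++xx)
          for (int yy = std::max(0, y - ry); yy <= std::min(ny - 1, y + ry); ++yy)
            for (int zz = std::max(0, z - rz); zz <= std::min(nz - 1, z + rz); ++zz)
              buf.push_back(img[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)]);
        size_t m = buf.size();
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
        double med = buf[m / 2];
        if (m % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + m / 2 - 1, buf.end());
          med = 0.5 * (med + buf[m / 2 - 1]);
        }
        out[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = med;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Minimum physical distance from arbitrary points to foreground voxel centers.
// points: m x 3 matrix of physical (x, y, z) coordinates in micrometres.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".minDistToForeground")]]
NumericVector min_dist_fg_cpp(NumericMatrix points, IntegerVector mask,
                              IntegerVector dims,
                              double dz, double dy, double dx) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  int m = points.nrow();
  NumericVector out(m, INF);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        if (!mask[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)]) continue;
        double px = x * dx, py = y * dy, pz = z * dz;
        for (int i = 0; i < m; ++i) {
          double ddx = points(i, 0) - px;
          double ddy = points(i, 1) - py;
          double ddz = points(i, 2) - pz;
          double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
          if (d2 < out[i]) out[i] = d2;
        }
      }
  for (int i = 0; i < m; ++i) out[i] = std::sqrt(out[i]);
  return out;
}
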