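// Mask utilities: anisotropic 3D Euclidean distance transform
// (Felzenszwalb-Huttenlocher separable lower envelope), 26-connected
// component labelling, marching-tetrahedra isosurface area, and trilinear
// resampling used by the augmentation step.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

static void edt_1d(const std::vector<double> &f, std::vector<double> &d,
                   double w2, int n) {
  // squared distance transform of a sampled function, sample spacing^2 = w2
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) / (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = w2 * (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Distance (mm) from each foreground voxel to the nearest background voxel
// centre; 0 on background. voxel = (dx, dy, dz) in mm.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims, NumericVector voxel) {
  const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  const double INF = 1e30;
  std::vector<double> d((R_xlen_t)n0 * n1 * n2);
  for (R_xlen_t i = 0; i < d.size(); ++i) d[i] = mask[i] ? INF : 0.0;
  std::vector<double> f, out;
  // axis 0
  f.resize(n0); out.resize(n0);
  for (int z = 0; z < n2; ++z)
    for (int y = 0; y < n1; ++y) {
      double *line = &d[((R_xlen_t)z * n1 + y) * n0];
      for (int i = 0; i < n0; ++i) f[i] = line[i];
      edt_1d(f, out, voxel[0] * voxel[0], n0);
      for (int i = 0; i < n0; ++i) line[i] = out[i];
    }
  // axis 1
  f.resize(n1); out.resize(n1);
  for (int z = 0; z < n2; ++z)
    for (int x = 0; x < n0; ++x) {
      for (int y = 0; y < n1; ++y) f[y] = d[((R_xlen_t)z * n1 + y) * n0 + x];
      edt_1d(f, out, voxel[1] * voxel[1], n1);
      for (int y = 0; y < n1; ++y) d[((R_xlen_t)z * n1 + y) * n0 + x] = out[y];
    }
  // axis 2
  f.resize(n2); out.resize(n2);
  for (int y = 0; y < n1; ++y)
    for (int x = 0; x < n0; ++x) {
      for (int z = 0; z < n2; ++z) f[z] = d[((R_xlen_t)z * n1 + y) * n0 + x];
      edt_1d(f, out, voxel[2] * voxel[2], n2);
      for (int z = 0; z < n2; ++z) d[((R_xlen_t)z * n1 + y) * n0 + x] = out[z];
    }
  NumericVector res(d.size());
  for (R_xlen_t i = 0; i < (R_xlen_t)d.size(); ++i) res[i] = std::sqrt(d[i]);
  res.attr("dim") = dims;
  return res;
}

// 26-connected component labels (0 = background), BFS.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dims) {
  const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  IntegerVector lab((R_xlen_t)n0 * n1 * n2);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < lab.size(); ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next; q.push(s);
    while (!q.empty()) {
      R_xlen_t c = q.front(); q.pop();
      const int x = c % n0, y = (c / n0) % n1, z = c / ((R_xlen_t)n0 * n1);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dxo = -1; dxo <= 1; ++dxo) {
            if (!dxo && !dy && !dz) continue;
            const int xx = x + dxo, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= n0 || yy >= n1 || zz >= n2) continue;
            const R_xlen_t idx = ((R_xlen_t)zz * n1 + yy) * n0 + xx;
            if (mask[idx] && lab[idx] == 0) { lab[idx] = next; q.push(idx); }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Marching tetrahedra: total isosurface area (mm^2) of field at `level`.
// Each grid cell is split into 6 tetrahedra; crossing points are linearly
// interpolated. voxel = spacing (mm) per axis.
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7}, {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};
// cube corner offsets (x, y, z)
static const int CORN[8][3] = {
  {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}
};

static inline double tri_area(const double a[3], const double b[3], const double c[3]) {
  double u[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
  double v[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
  double w0 = u[1]*v[2]-u[2]*v[1], w1 = u[2]*v[0]-u[0]*v[2], w2 = u[0]*v[1]-u[1]*v[0];
  return 0.5 * std::sqrt(w0*w0 + w1*w1 + w2*w2);
}

// [[Rcpp::export]]
double cpp_surface_area(NumericVector field, IntegerVector dims,
                        NumericVector voxel, double level) {
  const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  double area = 0.0;
  double val[8]; double pos[8][3];
  for (int z = 0; z < n2 - 1; ++z)
    for (int y = 0; y < n1 - 1; ++y)
      for (int x = 0; x < n0 - 1; ++x) {
        bool any_lo = false, any_hi = false;
        for (int c = 0; c < 8; ++c) {
          const int xx = x + CORN[c][0], yy = y + CORN[c][1], zz = z + CORN[c][2];
          val[c] = field[((R_xlen_t)zz * n1 + yy) * n0 + xx];
          pos[c][0] = xx * voxel[0]; pos[c][1] = yy * voxel[1]; pos[c][2] = zz * voxel[2];
          if (val[c] < level) any_lo = true; else any_hi = true;
        }
        if (!any_lo || !any_hi) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = TETS[t];
          int inside[4]; int nin = 0;
          for (int v = 0; v < 4; ++v) { inside[v] = val[T[v]] >= level; nin += inside[v]; }
          if (nin == 0 || nin == 4) continue;
          // collect crossing points on edges between differing vertices
          double pts[4][3]; int npts = 0;
          for (int a = 0; a < 4; ++a)
            for (int b = a + 1; b < 4; ++b) {
              if (inside[a] == inside[b]) continue;
              const double va = val[T[a]], vb = val[T[b]];
              const double w = (level - va) / (vb - va);
              for (int d = 0; d < 3; ++d)
                pts[npts][d] = pos[T[a]][d] + w * (pos[T[b]][d] - pos[T[a]][d]);
              ++npts;
            }
          if (npts == 3) area += tri_area(pts[0], pts[1], pts[2]);
          else if (npts == 4) {
            // quad: split into two triangles sharing the diagonal 0-2 or 0-3;
            // order points so the quad is convex: edges from the 2-2 split
            // come in the order (a0b0, a0b1, a1b0, a1b1) -> 0,1,3,2 cycle
            area += tri_area(pts[0], pts[1], pts[3]);
            area += tri_area(pts[0], pts[3], pts[2]);
          }
        }
      }
  return area;
}

// Trilinear resample about the array centre: out(p) = in(centre + (p-centre)/f),
// clamped to the boundary (replicate edges). f < 1 shrinks content.
// [[Rcpp::export]]
NumericVector cpp_rescale3(NumericVector img, IntegerVector dims, double factor) {
  const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  NumericVector out((R_xlen_t)n0 * n1 * n2);
  const double c0 = 0.5 * (n0 - 1), c1 = 0.5 * (n1 - 1), c2 = 0.5 * (n2 - 1);
  for (int z = 0; z < n2; ++z)
    for (int y = 0; y < n1; ++y)
      for (int x = 0; x < n0; ++x) {
        double sx = c0 + (x - c0) / factor;
        double sy = c1 + (y - c1) / factor;
        double sz = c2 + (z - c2) / factor;
        sx = std::min(std::max(sx, 0.0), (double)(n0 - 1));
        sy = std::min(std::max(sy, 0.0), (double)(n1 - 1));
        sz = std::min(std::max(sz, 0.0), (double)(n2 - 1));
        const int x0 = std::min((int)sx, n0 - 2 >= 0 ? n0 - 2 : 0);
        const int y0 = std::min((int)sy, n1 - 2 >= 0 ? n1 - 2 : 0);
        const int z0 = std::min((int)sz, n2 - 2 >= 0 ? n2 - 2 : 0);
        const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
        double acc = 0.0;
        for (int kz = 0; kz <= 1; ++kz)
          for (int ky = 0; ky <= 1; ++ky)
            for (int kx = 0; kx <= 1; ++kx) {
              const double w = (kx ? fx : 1 - fx) * (ky ? fy : 1 - fy) * (kz ? fz : 1 - fz);
              if (w == 0.0) continue;
              const int xx = std::min(x0 + kx, n0 - 1);
              const int yy = std::min(y0 + ky, n1 - 1);
              const int zz = std::min(z0 + kz, n2 - 1);
              acc += w * img[((R_xlen_t)zz * n1 + yy) * n0 + xx];
            }
        out[((R_xlen_t)z * n1 + y) * n0 + x] = acc;
      }
  out.attr("dim") = dims;
  return out;
}
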