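#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Arrays are column-major with dim (nz, ny, nx); linear index
// l = z + nz * (y + ny * x), all 0-based.

static inline int lin(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// 6-connected component labelling of a logical 3D array (iterative BFS).
// [[Rcpp::export(name = ".cc_label3")]]
IntegerVector cc_label3(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int start = 0; start < n; ++start) {
    if (!mask[start] || lab[start]) continue;
    ++next;
    lab[start] = next;
    stack.push_back(start);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int z = v % nz, r = v / nz, y = r % ny, x = r / ny;
      const int dz[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dx[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        int w = lin(zz, yy, xx, nz, ny);
        if (mask[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

static inline double trilin(const NumericVector &v, double z, double y,
                            double x, int nz, int ny, int nx, bool *ok) {
  if (z < 0 || y < 0 || x < 0 || z > nz - 1 || y > ny - 1 || x > nx - 1) {
    *ok = false;
    return 0.0;
  }
  *ok = true;
  int z0 = (int)std::floor(z), y0 = (int)std::floor(y), x0 = (int)std::floor(x);
  if (z0 == nz - 1) z0--;
  if (y0 == ny - 1) y0--;
  if (x0 == nx - 1) x0--;
  if (z0 < 0) z0 = 0;
  if (y0 < 0) y0 = 0;
  if (x0 < 0) x0 = 0;
  double fz = z - z0, fy = y - y0, fx = x - x0;
  double acc = 0.0;
  for (int dz = 0; dz <= 1; ++dz)
    for (int dy = 0; dy <= 1; ++dy)
      for (int dx = 0; dx <= 1; ++dx) {
        double w = (dz ? fz : 1 - fz) * (dy ? fy : 1 - fy) * (dx ? fx : 1 - fx);
        if (w > 0)
          acc += w * v[lin(z0 + dz, y0 + dy, x0 + dx, nz, ny)];
      }
  return acc;
}

// Gamma index for a set of evaluated voxels. Candidate offsets (mm, columns
// z/y/x) must be sorted by ascending Euclidean norm; the distance-squared
// early exit then cannot change the minimum. Offsets falling outside the
// grid are skipped (no extrapolation).
// [[Rcpp::export(name = ".gamma_search")]]
NumericVector gamma_search(NumericVector ref, NumericVector ev,
                           IntegerVector dims, NumericVector spacing,
                           IntegerVector voxels, NumericMatrix offsets,
                           NumericVector offnorm, double dd_abs, double dta) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  const int nv = voxels.size(), K = offsets.nrow();
  NumericVector out(nv);
  for (int i = 0; i < nv; ++i) {
    int v = voxels[i];
    int z = v % nz, r = v / nz, y = r % ny, x = r / ny;
    double rv = ref[v];
    double best = R_PosInf;
    for (int k = 0; k < K; ++k) {
      double dist2 = (offnorm[k] / dta) * (offnorm[k] / dta);
      if (dist2 >= best) break;
      bool ok;
      double e = trilin(ev, z + offsets(k, 0) / sz, y + offsets(k, 1) / sy,
                        x + offsets(k, 2) / sx, nz, ny, nx, &ok);
      if (!ok) continue;
      double dd = (e - rv) / dd_abs;
      double g2 = dd * dd + dist2;
      if (g2 < best) best = g2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Radiological depth (integral of RED along the ray, mm) from the grid
// boundary to each target voxel centre, marching upstream (-dir) with exact
// Siddon-style plane crossings. dir is a unit vector in (z, y, x) order.
// [[Rcpp::export(name = ".ray_depth")]]
NumericVector ray_depth(NumericVector red, IntegerVector dims,
                        NumericVector spacing, NumericVector dir,
                        IntegerVector voxels) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  const int nd[3] = {nz, ny, nx};
  double d[3] = {-dir[0], -dir[1], -dir[2]}; // march upstream
  const int nv = voxels.size();
  NumericVector out(nv);
  for (int i = 0; i < nv; ++i) {
    int v = voxels[i];
    int idx[3];
    idx[0] = v % nz;
    int r = v / nz;
    idx[1] = r % ny;
    idx[2] = r / ny;
    // physical position of voxel centre (origin cancels along the ray)
    double pos[3] = {idx[0] * sp[0], idx[1] * sp[1], idx[2] * sp[2]};
    int cur[3] = {idx[0], idx[1], idx[2]};
    // parametric distance to the next voxel face along each axis
    double tnext[3], tstep[3];
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(d[a]) < 1e-12) {
        tnext[a] = R_PosInf;
        tstep[a] = R_PosInf;
      } else {
        tstep[a] = sp[a] / std::fabs(d[a]);
        double face = (d[a] > 0) ? (cur[a] + 0.5) * sp[a] : (cur[a] - 0.5) * sp[a];
        tnext[a] = (face - pos[a]) / d[a];
        if (tnext[a] < 0) tnext[a] = 0; // numerical guard
      }
    }
    double depth = 0.0, t = 0.0;
    while (true) {
      int a = 0;
      if (tnext[1] < tnext[a]) a = 1;
      if (tnext[2] < tnext[a]) a = 2;
      double tn = tnext[a];
      depth += red[lin(cur[0], cur[1], cur[2], nz, ny)] * (tn - t);
      t = tn;
      cur[a] += (d[a] > 0) ? 1 : -1;
      if (cur[a] < 0 || cur[a] >= nd[a]) break;
      tnext[a] += tstep[a];
    }
    out[i] = depth;
  }
  return out;
}
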