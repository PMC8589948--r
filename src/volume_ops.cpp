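#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline R_xlen_t id3(int z, int y, int x, int Z, int Y) {
  return (R_xlen_t)z + (R_xlen_t)Z * ((R_xlen_t)y + (R_xlen_t)Y * (R_xlen_t)x);
}

// Connected-component labeling of a binary volume, 6 or 26 connectivity.
// Labels components 1..k in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, int connectivity) {
  IntegerVector d = mask.attr("dim");
  const int Z = d[0], Y = d[1], X = d[2];
  IntegerVector lab((R_xlen_t)Z * Y * X);
  lab.attr("dim") = d;
  const int *mp = mask.begin();
  int *lp = lab.begin();
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (int xx = 0; xx < X; ++xx)
    for (int yy = 0; yy < Y; ++yy)
      for (int zz = 0; zz < Z; ++zz) {
        const R_xlen_t i0 = id3(zz, yy, xx, Z, Y);
        if (mp[i0] == 0 || lp[i0] != 0) continue;
        ++next;
        lp[i0] = next;
        stack.clear();
        stack.push_back(i0);
        while (!stack.empty()) {
          const R_xlen_t cur = stack.back();
          stack.pop_back();
          const int cx = (int)(cur / ((R_xlen_t)Z * Y));
          const int cy = (int)((cur / Z) % Y);
          const int cz = (int)(cur % Z);
          for (int dx = -1; dx <= 1; ++dx)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dz = -1; dz <= 1; ++dz) {
                if (dx == 0 && dy == 0 && dz == 0) continue;
                if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) > 1)
                  continue;
                const int nx = cx + dx, ny = cy + dy, nz = cz + dz;
                if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z)
                  continue;
                const R_xlen_t ni = id3(nz, ny, nx, Z, Y);
                if (mp[ni] != 0 && lp[ni] == 0) {
                  lp[ni] = next;
                  stack.push_back(ni);
                }
              }
        }
      }
  return lab;
}

// For each row of a (point set, columns = coordinates), the minimum
// Euclidean distance to any row of b.
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow(), k = a.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double s = 0;
      for (int c = 0; c < k; ++c) {
        const double d = a(i, c) - b(j, c);
        s += d * d;
      }
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

static inline double sample_tri(const double *xp, int Z, int Y, int X,
                                double sz, double sy, double sx, bool zero_outside) {
  if (zero_outside) {
    if (sz < -0.5 || sz > Z - 0.5 || sy < -0.5 || sy > Y - 0.5 ||
        sx < -0.5 || sx > X - 0.5)
      return 0.0;
  }
  int z0 = (int)std::floor(sz), y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
  const double fz = sz - z0, fy = sy - y0, fx = sx - x0;
  double acc = 0.0;
  for (int dx = 0; dx <= 1; ++dx)
    for (int dy = 0; dy <= 1; ++dy)
      for (int dz = 0; dz <= 1; ++dz) {
        const double wgt = (dz ? fz : 1 - fz) * (dy ? fy : 1 - fy) * (dx ? fx : 1 - fx);
        if (wgt == 0.0) continue;
        int z = z0 + dz, y = y0 + dy, x = x0 + dx;
        double v;
        if (z < 0 || z >= Z || y < 0 || y >= Y || x < 0 || x >= X) {
          if (zero_outside) { v = 0.0; }
          else {  // clamp to edge
            z = std::min(std::max(z, 0), Z - 1);
            y = std::min(std::max(y, 0), Y - 1);
            x = std::min(std::max(x, 0), X - 1);
            v = xp[id3(z, y, x, Z, Y)];
          }
        } else v = xp[id3(z, y, x, Z, Y)];
        acc += wgt * v;
      }
  return acc;
}

static inline double sample_nn(const double *xp, int Z, int Y, int X,
                               double sz, double sy, double sx, bool zero_outside) {
  const int z = (int)std::floor(sz + 0.5), y = (int)std::floor(sy + 0.5),
            x = (int)std::floor(sx + 0.5);
  if (z < 0 || z >= Z || y < 0 || y >= Y || x < 0 || x >= X) {
    if (zero_outside) return 0.0;
    return xp[id3(std::min(std::max(z, 0), Z - 1), std::min(std::max(y, 0), Y - 1),
                  std::min(std::max(x, 0), X - 1), Z, Y)];
  }
  return xp[id3(z, y, x, Z, Y)];
}

// Grid resampling with voxel-center alignment: input coordinate of output
// voxel i is (i + 0.5) * out_spacing / in_spacing - 0.5 per axis.
// mode: 0 = nearest, 1 = trilinear.  Edge-clamped.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector x, IntegerVector out_dim,
                           NumericVector in_spacing, NumericVector out_spacing,
                           int mode) {
  IntegerVector d = x.attr("dim");
  const int Z = d[0], Y = d[1], X = d[2];
  const int Zo = out_dim[0], Yo = out_dim[1], Xo = out_dim[2];
  const double rz = out_spacing[0] / in_spacing[0],
               ry = out_spacing[1] / in_spacing[1],
               rx = out_spacing[2] / in_spacing[2];
  NumericVector out((R_xlen_t)Zo * Yo * Xo);
  out.attr("dim") = out_dim;
  const double *xp = x.begin();
  double *op = out.begin();
  for (int xx = 0; xx < Xo; ++xx) {
    const double sx = (xx + 0.5) * rx - 0.5;
    for (int yy = 0; yy < Yo; ++yy) {
      const double sy = (yy + 0.5) * ry - 0.5;
      for (int zz = 0; zz < Zo; ++zz) {
        const double sz = (zz + 0.5) * rz - 0.5;
        op[id3(zz, yy, xx, Zo, Yo)] =
            mode == 0 ? sample_nn(xp, Z, Y, X, sz, sy, sx, false)
                      : sample_tri(xp, Z, Y, X, sz, sy, sx, false);
      }
    }
  }
  return out;
}

// Backward warp: output voxel i takes the value of the input sampled at
// i + displacement(i) (voxel units).  Outside the input -> 0.
// mode: 0 = nearest, 1 = trilinear.
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector x, NumericVector dz, NumericVector dy,
                       NumericVector dx, int mode) {
  IntegerVector d = x.attr("dim");
  const int Z = d[0], Y = d[1], X = d[2];
  NumericVector out((R_xlen_t)Z * Y * X);
  out.attr("dim") = d;
  const double *xp = x.begin(), *pz = dz.begin(), *py = dy.begin(), *px = dx.begin();
  double *op = out.begin();
  for (int xx = 0; xx < X; ++xx)
    for (int yy = 0; yy < Y; ++yy)
      for (int zz = 0; zz < Z; ++zz) {
        const R_xlen_t i = id3(zz, yy, xx, Z, Y);
        const double sz = zz + pz[i], sy = yy + py[i], sx = xx + px[i];
        op[i] = mode == 0 ? sample_nn(xp, Z, Y, X, sz, sy, sx, true)
                          : sample_tri(xp, Z, Y, X, sz, sy, sx, true);
      }
  return out;
}
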