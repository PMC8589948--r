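#include <Rcpp.h>
using namespace Rcpp;

// Tensors are R arrays in (z, y, x, channel) order, z fastest (column-major).
// Weights are (kz, ky, kx, c_in, c_out).  All kernels assume odd spatial
// kernel extents and "same" zero padding.

static inline R_xlen_t id4(int z, int y, int x, int c, int Z, int Y, int X) {
  return (R_xlen_t)z +
         (R_xlen_t)Z * ((R_xlen_t)y + (R_xlen_t)Y * ((R_xlen_t)x + (R_xlen_t)X * (R_xlen_t)c));
}

static inline R_xlen_t idw(int dz, int dy, int dx, int ci, int co,
                           int kz, int ky, int kx, int Ci) {
  return (R_xlen_t)dz +
         (R_xlen_t)kz * ((R_xlen_t)dy +
         (R_xlen_t)ky * ((R_xlen_t)dx +
         (R_xlen_t)kx * ((R_xlen_t)ci + (R_xlen_t)Ci * (R_xlen_t)co)));
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int Z = xd[0], Y = xd[1], X = xd[2], Ci = xd[3];
  const int kz = wd[0], ky = wd[1], kx = wd[2], Co = wd[4];
  if (wd[3] != Ci) stop("conv: channel mismatch");
  const int pz = kz / 2, py = ky / 2, px = kx / 2;
  NumericVector out((R_xlen_t)Z * Y * X * Co);
  out.attr("dim") = IntegerVector::create(Z, Y, X, Co);
  const double *xp = x.begin(), *wp = w.begin(), *bp = b.begin();
  double *op = out.begin();
  for (int co = 0; co < Co; ++co)
    for (int xx = 0; xx < X; ++xx)
      for (int yy = 0; yy < Y; ++yy)
        for (int zz = 0; zz < Z; ++zz) {
          double acc = bp[co];
          for (int ci = 0; ci < Ci; ++ci)
            for (int dx = 0; dx < kx; ++dx) {
              const int sx = xx + dx - px;
              if (sx < 0 || sx >= X) continue;
              for (int dy = 0; dy < ky; ++dy) {
                const int sy = yy + dy - py;
                if (sy < 0 || sy >= Y) continue;
                for (int dz = 0; dz < kz; ++dz) {
                  const int sz = zz + dz - pz;
                  if (sz < 0 || sz >= Z) continue;
                  acc += xp[id4(sz, sy, sx, ci, Z, Y, X)] *
                         wp[idw(dz, dy, dx, ci, co, kz, ky, kx, Ci)];
                }
              }
            }
          op[id4(zz, yy, xx, co, Z, Y, X)] = acc;
        }
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int Z = xd[0], Y = xd[1], X = xd[2], Ci = xd[3];
  const int kz = wd[0], ky = wd[1], kx = wd[2], Co = wd[4];
  const int pz = kz / 2, py = ky / 2, px = kx / 2;
  NumericVector gx((R_xlen_t)Z * Y * X * Ci), gw(w.size()), gb(Co);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  const double *xp = x.begin(), *wp = w.begin(), *gp = gy.begin();
  double *gxp = gx.begin(), *gwp = gw.begin(), *gbp = gb.begin();
  for (int co = 0; co < Co; ++co)
    for (int xx = 0; xx < X; ++xx)
      for (int yy = 0; yy < Y; ++yy)
        for (int zz = 0; zz < Z; ++zz) {
          const double g = gp[id4(zz, yy, xx, co, Z, Y, X)];
          if (g == 0.0) continue;
          gbp[co] += g;
          for (int ci = 0; ci < Ci; ++ci)
            for (int dx = 0; dx < kx; ++dx) {
              const int sx = xx + dx - px;
              if (sx < 0 || sx >= X) continue;
              for (int dy = 0; dy < ky; ++dy) {
                const int sy = yy + dy - py;
                if (sy < 0 || sy >= Y) continue;
                for (int dz = 0; dz < kz; ++dz) {
                  const int sz = zz + dz - pz;
                  if (sz < 0 || sz >= Z) continue;
                  const R_xlen_t xi = id4(sz, sy, sx, ci, Z, Y, X);
                  const R_xlen_t wi = idw(dz, dy, dx, ci, co, kz, ky, kx, Ci);
                  gwp[wi] += xp[xi] * g;
                  gxp[xi] += wp[wi] * g;
                }
              }
            }
        }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Max pooling with window (pz, py, px), each 1 or 2; spatial dims must be
// divisible by the window.  Returns pooled values and 0-based argmax linear
// indices into the input (ties -> first in column-major order).
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int pz, int py, int px) {
  IntegerVector xd = x.attr("dim");
  const int Z = xd[0], Y = xd[1], X = xd[2], C = xd[3];
  const int Zo = Z / pz, Yo = Y / py, Xo = X / px;
  NumericVector out((R_xlen_t)Zo * Yo * Xo * C);
  NumericVector idx((R_xlen_t)Zo * Yo * Xo * C);
  out.attr("dim") = IntegerVector::create(Zo, Yo, Xo, C);
  idx.attr("dim") = IntegerVector::create(Zo, Yo, Xo, C);
  const double *xp = x.begin();
  double *op = out.begin(), *ip = idx.begin();
  for (int c = 0; c < C; ++c)
    for (int xo = 0; xo < Xo; ++xo)
      for (int yo = 0; yo < Yo; ++yo)
        for (int zo = 0; zo < Zo; ++zo) {
          double best = R_NegInf;
          R_xlen_t bi = 0;
          for (int dx = 0; dx < px; ++dx)
            for (int dy = 0; dy < py; ++dy)
              for (int dz = 0; dz < pz; ++dz) {
                const R_xlen_t xi =
                    id4(zo * pz + dz, yo * py + dy, xo * px + dx, c, Z, Y, X);
                if (xp[xi] > best) { best = xp[xi]; bi = xi; }
              }
          const R_xlen_t oi = id4(zo, yo, xo, c, Zo, Yo, Xo);
          op[oi] = best;
          ip[oi] = (double)bi;
        }
  return List::create(_["y"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector idx, NumericVector gy,
                              IntegerVector xdim) {
  NumericVector gx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  const double *ip = idx.begin(), *gp = gy.begin();
  double *gxp = gx.begin();
  const R_xlen_t n = gy.size();
  for (R_xlen_t i = 0; i < n; ++i) gxp[(R_xlen_t)ip[i]] += gp[i];
  return gx;
}
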