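// Native tensor kernels for the anisotropic segmentation networks.
// Arrays are R numeric arrays in column-major order with dims
// (nx, ny, nz, C); weights (kx, ky, kz, Cin, Cout).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int idx4(int x, int y, int z, int c, int nx, int ny, int nz) {
  return x + nx * (y + ny * (z + (long)nz * c));
}

// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector x, IntegerVector xdim,
                         NumericVector W, IntegerVector wdim,
                         NumericVector b,
                         IntegerVector dil, int stride_xy,
                         IntegerVector pad_lo) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], ci_n = xdim[3];
  const int kx = wdim[0], ky = wdim[1], kz = wdim[2], co_n = wdim[4];
  const int dx = dil[0], dy = dil[1], dz = dil[2];
  const int plx = pad_lo[0], ply = pad_lo[1], plz = pad_lo[2];
  const int ox = (stride_xy == 1) ? nx : (nx + 1) / 2;
  const int oy = (stride_xy == 1) ? ny : (ny + 1) / 2;
  const int oz = nz;
  NumericVector out(R_xlen_t(ox) * oy * oz * co_n);
  const double *px = x.begin(), *pw = W.begin();
  double *po = out.begin();
  for (int co = 0; co < co_n; ++co) {
    const double bias = b[co];
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int xo = 0; xo < ox; ++xo) {
          double acc = bias;
          const int bx = xo * stride_xy - plx;
          const int by = y * stride_xy - ply;
          const int bz = z - plz;
          for (int ci = 0; ci < ci_n; ++ci)
            for (int tz = 0; tz < kz; ++tz) {
              const int iz = bz + tz * dz;
              if (iz < 0 || iz >= nz) continue;
              for (int ty = 0; ty < ky; ++ty) {
                const int iy = by + ty * dy;
                if (iy < 0 || iy >= ny) continue;
                for (int tx = 0; tx < kx; ++tx) {
                  const int ix = bx + tx * dx;
                  if (ix < 0 || ix >= nx) continue;
                  acc += pw[tx + kx * (ty + ky * (tz + (long)kz * (ci + (long)ci_n * co)))] *
                         px[idx4(ix, iy, iz, ci, nx, ny, nz)];
                }
              }
            }
          po[idx4(xo, y, z, co, ox, oy, oz)] = acc;
        }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz, co_n);
  return out;
}

// [[Rcpp::export]]
List conv3d_bwd(NumericVector x, IntegerVector xdim,
                NumericVector W, IntegerVector wdim,
                NumericVector gout,
                IntegerVector dil, int stride_xy,
                IntegerVector pad_lo, bool need_gx) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], ci_n = xdim[3];
  const int kx = wdim[0], ky = wdim[1], kz = wdim[2], co_n = wdim[4];
  const int dx = dil[0], dy = dil[1], dz = dil[2];
  const int plx = pad_lo[0], ply = pad_lo[1], plz = pad_lo[2];
  const int ox = (stride_xy == 1) ? nx : (nx + 1) / 2;
  const int oy = (stride_xy == 1) ? ny : (ny + 1) / 2;
  const int oz = nz;
  NumericVector gx(need_gx ? x.size() : 0);
  NumericVector gW(W.size());
  NumericVector gb(co_n);
  const double *px = x.begin(), *pw = W.begin(), *pg = gout.begin();
  double *pgx = gx.begin(), *pgw = gW.begin();
  for (int co = 0; co < co_n; ++co) {
    double gbacc = 0.0;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int xo = 0; xo < ox; ++xo) {
          const double g = pg[idx4(xo, y, z, co, ox, oy, oz)];
          if (g == 0.0) { continue; }
          gbacc += g;
          const int bx = xo * stride_xy - plx;
          const int by = y * stride_xy - ply;
          const int bz = z - plz;
          for (int ci = 0; ci < ci_n; ++ci)
            for (int tz = 0; tz < kz; ++tz) {
              const int iz = bz + tz * dz;
              if (iz < 0 || iz >= nz) continue;
              for (int ty = 0; ty < ky; ++ty) {
                const int iy = by + ty * dy;
                if (iy < 0 || iy >= ny) continue;
                for (int tx = 0; tx < kx; ++tx) {
                  const int ix = bx + tx * dx;
                  if (ix < 0 || ix >= nx) continue;
                  const long wi = tx + kx * (ty + ky * (tz + (long)kz * (ci + (long)ci_n * co)));
                  const long xi = idx4(ix, iy, iz, ci, nx, ny, nz);
                  pgw[wi] += g * px[xi];
                  if (need_gx) pgx[xi] += g * pw[wi];
                }
              }
            }
        }
    gb[co] = gbacc;
  }
  if (need_gx) gx.attr("dim") = xdim;
  gW.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// Transposed convolution, factor-2 in-plane upsampling with a 3x3x1 kernel.
// fine(ox,oy) = sum over coarse (mx,my) with ox-2mx, oy-2my in {-1,0,1}.
// Output in-plane dims are exactly twice the input dims.

// [[Rcpp::export]]
NumericVector deconv2x_fwd(NumericVector x, IntegerVector xdim,
                           NumericVector W, IntegerVector wdim,
                           NumericVector b) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], ci_n = xdim[3];
  const int co_n = wdim[4];
  const int ox = 2 * nx, oy = 2 * ny, oz = nz;
  NumericVector out(R_xlen_t(ox) * oy * oz * co_n);
  const double *px = x.begin(), *pw = W.begin();
  double *po = out.begin();
  for (int co = 0; co < co_n; ++co)
    for (int z = 0; z < oz; ++z)
      for (int yo = 0; yo < oy; ++yo)
        for (int xo = 0; xo < ox; ++xo) {
          double acc = b[co];
          for (int ty = -1; ty <= 1; ++ty) {
            if ((yo - ty) % 2 != 0) continue;
            const int my = (yo - ty) / 2;
            if (my < 0 || my >= ny) continue;
            for (int tx = -1; tx <= 1; ++tx) {
              if ((xo - tx) % 2 != 0) continue;
              const int mx = (xo - tx) / 2;
              if (mx < 0 || mx >= nx) continue;
              for (int ci = 0; ci < ci_n; ++ci)
                acc += pw[(tx + 1) + 3 * ((ty + 1) + 3 * (0 + 1 * (ci + (long)ci_n * co)))] *
                       px[idx4(mx, my, z, ci, nx, ny, nz)];
            }
          }
          po[idx4(xo, yo, z, co, ox, oy, oz)] = acc;
        }
  out.attr("dim") = IntegerVector::create(ox, oy, oz, co_n);
  return out;
}

// [[Rcpp::export]]
List deconv2x_bwd(NumericVector x, IntegerVector xdim,
                  NumericVector W, IntegerVector wdim,
                  NumericVector gout, bool need_gx) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], ci_n = xdim[3];
  const int co_n = wdim[4];
  const int ox = 2 * nx, oy = 2 * ny, oz = nz;
  NumericVector gx(need_gx ? x.size() : 0);
  NumericVector gW(W.size());
  NumericVector gb(co_n);
  const double *px = x.begin(), *pw = W.begin(), *pg = gout.begin();
  double *pgx = gx.begin(), *pgw = gW.begin();
  for (int co = 0; co < co_n; ++co) {
    double gbacc = 0.0;
    for (int z = 0; z < oz; ++z)
      for (int yo = 0; yo < oy; ++yo)
        for (int xo = 0; xo < ox; ++xo) {
          const double g = pg[idx4(xo, yo, z, co, ox, oy, oz)];
          if (g == 0.0) continue;
          gbacc += g;
          for (int ty = -1; ty <= 1; ++ty) {
            if ((yo - ty) % 2 != 0) continue;
            const int my = (yo - ty) / 2;
            if (my < 0 || my >= ny) continue;
            for (int tx = -1; tx <= 1; ++tx) {
              if ((xo - tx) % 2 != 0) continue;
              const int mx = (xo - tx) / 2;
              if (mx < 0 || mx >= nx) continue;
              for (int ci = 0; ci < ci_n; ++ci) {
                const long wi = (tx + 1) + 3 * ((ty + 1) + 3 * (0 + 1 * (ci + (long)ci_n * co)));
                const long xi = idx4(mx, my, z, ci, nx, ny, nz);
                pgw[wi] += g * px[xi];
                if (need_gx) pgx[xi] += g * pw[wi];
              }
            }
          }
        }
    gb[co] = gbacc;
  }
  if (need_gx) gx.attr("dim") = xdim;
  gW.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// Affine resampling: out(v) = in(M (v - c) + c), trilinear or nearest,
// zero outside the grid.  M is 3x3 (column-major), c the volume center.

// [[Rcpp::export]]
NumericVector affine_resample(NumericVector vol, IntegerVector vdim,
                              NumericVector M, NumericVector center,
                              int nearest) {
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  NumericVector out(vol.size());
  const double *pv = vol.begin();
  double *po = out.begin();
  const double m00 = M[0], m10 = M[1], m20 = M[2];
  const double m01 = M[3], m11 = M[4], m21 = M[5];
  const double m02 = M[6], m12 = M[7], m22 = M[8];
  const double cx = center[0], cy = center[1], cz = center[2];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const double vx = x - cx, vy = y - cy, vz = z - cz;
        const double sx = m00 * vx + m01 * vy + m02 * vz + cx;
        const double sy = m10 * vx + m11 * vy + m12 * vz + cy;
        const double sz = m20 * vx + m21 * vy + m22 * vz + cz;
        double val = 0.0;
        if (nearest) {
          const int ix = (int)std::lround(sx);
          const int iy = (int)std::lround(sy);
          const int iz = (int)std::lround(sz);
          if (ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 && iz < nz)
            val = pv[ix + nx * (iy + (long)ny * iz)];
        } else {
          const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy),
                    z0 = (int)std::floor(sz);
          const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
          for (int dz2 = 0; dz2 <= 1; ++dz2) {
            const int iz = z0 + dz2;
            if (iz < 0 || iz >= nz) continue;
            const double wz = dz2 ? fz : 1.0 - fz;
            for (int dy2 = 0; dy2 <= 1; ++dy2) {
              const int iy = y0 + dy2;
              if (iy < 0 || iy >= ny) continue;
              const double wy = dy2 ? fy : 1.0 - fy;
              for (int dx2 = 0; dx2 <= 1; ++dx2) {
                const int ix = x0 + dx2;
                if (ix < 0 || ix >= nx) continue;
                const double wx = dx2 ? fx : 1.0 - fx;
                val += wz * wy * wx * pv[ix + nx * (iy + (long)ny * iz)];
              }
            }
          }
        }
        po[x + nx * (y + (long)ny * z)] = val;
      }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// Pairwise Potts CRF, mean-field relaxation, binary labels.
// Kernel between voxels i, j:
//   k_ij = w_sp * exp(-d2/(2 sig_sp^2))
//        + w_app * exp(-d2/(2 sig_app_sp^2) - (I_i - I_j)^2/(2 sig_app_int^2))
// Messages are computed inside a truncated window of `radius` voxels; with a
// radius covering the grid the model is fully connected.

static inline double crf_kernel(double d2, double di,
                                double w_sp, double s_sp,
                                double w_app, double s_asp, double s_aint) {
  double k = 0.0;
  if (w_sp > 0) k += w_sp * std::exp(-d2 / (2.0 * s_sp * s_sp));
  if (w_app > 0)
    k += w_app * std::exp(-d2 / (2.0 * s_asp * s_asp) -
                          (di * di) / (2.0 * s_aint * s_aint));
  return k;
}

// [[Rcpp::export]]
NumericVector crf_meanfield(NumericVector unary, IntegerVector vdim,
                            NumericVector img,
                            double w_sp, double sig_sp,
                            double w_app, double sig_app_sp, double sig_app_int,
                            int radius, int iters, int init_uniform) {
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  const long n = (long)nx * ny * nz;
  // unary has dims (nx,ny,nz,2): -log prob per class
  NumericVector Q(n * 2);
  // init from unaries, or uniform (a second mean-field basin)
  for (long i = 0; i < n; ++i) {
    if (init_uniform) { Q[i] = 0.5; Q[i + n] = 0.5; continue; }
    const double e0 = std::exp(-unary[i]), e1 = std::exp(-unary[i + n]);
    Q[i] = e0 / (e0 + e1);
    Q[i + n] = e1 / (e0 + e1);
  }
  const double *pim = img.begin();
  for (int it = 0; it < iters; ++it) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const long i = x + nx * (y + (long)ny * z);
          double m0 = 0.0, m1 = 0.0;
          const double Ii = pim[i];
          for (int dz = -radius; dz <= radius; ++dz) {
            const int jz = z + dz;
            if (jz < 0 || jz >= nz) continue;
            for (int dy = -radius; dy <= radius; ++dy) {
              const int jy = y + dy;
              if (jy < 0 || jy >= ny) continue;
              for (int dx = -radius; dx <= radius; ++dx) {
                const int jx = x + dx;
                if (jx < 0 || jx >= nx) continue;
                if (dx == 0 && dy == 0 && dz == 0) continue;
                const long j = jx + nx * (jy + (long)ny * jz);
                const double d2 = (double)dx * dx + (double)dy * dy + (double)dz * dz;
                const double k = crf_kernel(d2, Ii - pim[j], w_sp, sig_sp,
                                            w_app, sig_app_sp, sig_app_int);
                m0 += k * Q[j];
                m1 += k * Q[j + n];
              }
            }
          }
          // Potts: energy of label l gets message mass of the other label.
          // Updates are sequential in place (coordinate-ascent mean field),
          // which converges monotonically unlike the parallel scheme.
          const double a0 = -unary[i] - m1;
          const double a1 = -unary[i + n] - m0;
          const double mx = std::max(a0, a1);
          const double e0 = std::exp(a0 - mx), e1 = std::exp(a1 - mx);
          Q[i] = e0 / (e0 + e1);
          Q[i + n] = e1 / (e0 + e1);
        }
  }
  Q.attr("dim") = IntegerVector::create(nx, ny, nz, 2);
  return Q;
}

// Potts energy of a labeling under the window-truncated model actually
// relaxed by crf_meanfield (used to pick among mean-field basins).

// [[Rcpp::export]]
double crf_energy_window(IntegerVector labels, NumericVector unary,
                         IntegerVector vdim, NumericVector img,
                         double w_sp, double sig_sp,
                         double w_app, double sig_app_sp, double sig_app_int,
                         int radius) {
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  const long n = (long)nx * ny * nz;
  double E = 0.0;
  for (long i = 0; i < n; ++i) E += unary[i + n * labels[i]];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const long i = x + nx * (y + (long)ny * z);
        for (int dz = 0; dz <= radius; ++dz) {
          const int jz = z + dz;
          if (jz >= nz) continue;
          for (int dy = (dz == 0 ? 0 : -radius); dy <= radius; ++dy) {
            const int jy = y + dy;
            if (jy < 0 || jy >= ny) continue;
            for (int dx = ((dz == 0 && dy == 0) ? 1 : -radius); dx <= radius; ++dx) {
              const int jx = x + dx;
              if (jx < 0 || jx >= nx) continue;
              const long j = jx + nx * (jy + (long)ny * jz);
              if (labels[i] == labels[j]) continue;
              const double d2 = (double)dx * dx + (double)dy * dy + (double)dz * dz;
              E += crf_kernel(d2, img[i] - img[j], w_sp, sig_sp,
                              w_app, sig_app_sp, sig_app_int);
            }
          }
        }
      }
  return E;
}

// Exact Potts energy of a labeling under the same dense model (no window
// truncation); used as an enumeration oracle on tiny instances.

// [[Rcpp::export]]
double crf_energy(IntegerVector labels, NumericVector unary, IntegerVector vdim,
                  NumericVector img,
                  double w_sp, double sig_sp,
                  double w_app, double sig_app_sp, double sig_app_int) {
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  const long n = (long)nx * ny * nz;
  double E = 0.0;
  for (long i = 0; i < n; ++i) E += unary[i + n * labels[i]];
  for (long i = 0; i < n; ++i) {
    const int xi = i % nx, yi = (i / nx) % ny, zi = i / ((long)nx * ny);
    for (long j = i + 1; j < n; ++j) {
      if (labels[i] == labels[j]) continue;
      const int xj = j % nx, yj = (j / nx) % ny, zj = j / ((long)nx * ny);
      const double d2 = (double)(xi - xj) * (xi - xj) +
                        (double)(yi - yj) * (yi - yj) +
                        (double)(zi - zj) * (zi - zj);
      E += crf_kernel(d2, img[i] - img[j], w_sp, sig_sp,
                      w_app, sig_app_sp, sig_app_int);
    }
  }
  return E;
}

// Directed minimum Euclidean distances from each point of A to the set B,
// in millimetres given per-axis spacing.

// [[Rcpp::export]]
NumericVector directed_surface_dists(NumericMatrix A, NumericMatrix B,
                                     NumericVector spacing) {
  const int na = A.nrow(), nb = B.nrow();
  NumericVector d(na);
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    const double ax = A(i, 0) * sx, ay = A(i, 1) * sy, az = A(i, 2) * sz;
    for (int j = 0; j < nb; ++j) {
      const double dx = ax - B(j, 0) * sx;
      const double dy = ay - B(j, 1) * sy;
      const double dz = az - B(j, 2) * sz;
      const double dd = dx * dx + dy * dy + dz * dz;
      if (dd < best) best = dd;
    }
    d[i] = std::sqrt(best);
  }
  return d;
}
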