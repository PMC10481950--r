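// Low-level grid kernels: direct 3x3x3 convolution with exact gradients,
// trilinear interpolation with gradients, 2x max-pooling / nearest
// upsampling, and separable box sums. All arrays are R column-major with dim
// (nx, ny, nz, C); voxel indices are 0-based in C++.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Direct 3x3x3 'same' convolution with zero padding, channel-last
// volumes (nx,ny,nz,C) and weights (3,3,3,Cin,Cout) in R's flattening
// order. Per output line, all 27 stencil taps are applied while the
// neighbouring input lines are cache resident; no im2col matrix is
// materialised (allocation traffic dominates at these sizes on one core).
// [[Rcpp::export]]
NumericVector cpp_conv3_fwd(NumericVector x, IntegerVector dim,
                            NumericVector W, NumericVector b) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], Cin = dim[3];
  const int M = nx * ny * nz;
  const int Cout = b.size();
  NumericVector out((size_t)M * Cout);
  out.attr("dim") = IntegerVector::create(nx, ny, nz, Cout);
  const double* xp = REAL(x);
  const double* wp = REAL(W);
  double* op = REAL(out);
  for (int co = 0; co < Cout; ++co) {
    double* oc = op + (size_t)co * M;
    std::fill(oc, oc + M, b[co]);
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = xp + (size_t)ci * M;
      const double* w = wp + 27 * (ci + (size_t)Cin * co);
      for (int k = 0; k < nz; ++k) {
        for (int j = 0; j < ny; ++j) {
          double* dst = oc + idx3(0, j, k, nx, ny);
          for (int dz = -1; dz <= 1; ++dz) {
            const int kk = k + dz;
            if (kk < 0 || kk >= nz) continue;
            for (int dy = -1; dy <= 1; ++dy) {
              const int jj = j + dy;
              if (jj < 0 || jj >= ny) continue;
              const double* src = xc + idx3(0, jj, kk, nx, ny);
              const double* wrow = w + 3 * (dy + 1) + 9 * (dz + 1);
              const double wm = wrow[0], w0 = wrow[1], wpz = wrow[2];
              if (nx == 1) { dst[0] += w0 * src[0]; continue; }
              dst[0] += w0 * src[0] + wpz * src[1];
              for (int i = 1; i < nx - 1; ++i)
                dst[i] += wm * src[i - 1] + w0 * src[i] + wpz * src[i + 1];
              dst[nx - 1] += wm * src[nx - 2] + w0 * src[nx - 1];
            }
          }
        }
      }
    }
  }
  return out;
}

// Gradients of cpp_conv3_fwd w.r.t. input, weights and bias, with the
// same line-resident loop structure.
// [[Rcpp::export]]
List cpp_conv3_bwd(NumericVector x, IntegerVector dim, NumericVector W,
                   IntegerVector wdim, NumericVector gout) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], Cin = dim[3];
  const int M = nx * ny * nz;
  const int Cout = wdim[4];
  NumericVector dx_((size_t)M * Cin);
  dx_.attr("dim") = dim;
  NumericVector dW(W.size());
  dW.attr("dim") = wdim;
  NumericVector db(Cout);
  const double* xp = REAL(x);
  const double* wp = REAL(W);
  const double* gp = REAL(gout);
  double* dxp = REAL(dx_);
  double* dwp = REAL(dW);
  for (int co = 0; co < Cout; ++co) {
    const double* gc = gp + (size_t)co * M;
    double s = 0.0;
    for (int m = 0; m < M; ++m) s += gc[m];
    db[co] = s;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = xp + (size_t)ci * M;
      double* dxc = dxp + (size_t)ci * M;
      const double* w = wp + 27 * (ci + (size_t)Cin * co);
      double* dw = dwp + 27 * (ci + (size_t)Cin * co);
      for (int k = 0; k < nz; ++k) {
        for (int j = 0; j < ny; ++j) {
          const double* g = gc + idx3(0, j, k, nx, ny);
          for (int dz = -1; dz <= 1; ++dz) {
            const int kk = k + dz;
            if (kk < 0 || kk >= nz) continue;
            for (int dy = -1; dy <= 1; ++dy) {
              const int jj = j + dy;
              if (jj < 0 || jj >= ny) continue;
              const double* src = xc + idx3(0, jj, kk, nx, ny);
              double* dst = dxc + idx3(0, jj, kk, nx, ny);
              const int off = 3 * (dy + 1) + 9 * (dz + 1);
              const double wm = w[off], w0 = w[off + 1], wpz = w[off + 2];
              double am = 0.0, a0 = 0.0, ap = 0.0;
              if (nx == 1) {
                dw[off + 1] += src[0] * g[0];
                dst[0] += w0 * g[0];
                continue;
              }
              // dx = -1 tap pairs g[i] with src[i-1]; dx = +1 with src[i+1]
              a0 += src[0] * g[0];
              ap += src[1] * g[0];
              dst[0] += w0 * g[0] + wm * g[1];
              for (int i = 1; i < nx - 1; ++i) {
                const double gi = g[i];
                am += src[i - 1] * gi;
                a0 += src[i] * gi;
                ap += src[i + 1] * gi;
                dst[i] += wpz * g[i - 1] + w0 * gi + wm * g[i + 1];
              }
              const double gl = g[nx - 1];
              am += src[nx - 2] * gl;
              a0 += src[nx - 1] * gl;
              dst[nx - 1] += wpz * g[nx - 2] + w0 * gl;
              dw[off] += am;
              dw[off + 1] += a0;
              dw[off + 2] += ap;
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx_, _["dW"] = dW, _["db"] = db);
}

struct Cell {
  int i0, i1, j0, j1, k0, k1;
  double fx, fy, fz;
  bool cx, cy, cz;  // clamped -> zero derivative along that axis
};

static inline void locate(double p, int n, int& a0, int& a1, double& f, bool& cl) {
  cl = false;
  if (n == 1) { a0 = 0; a1 = 0; f = 0.0; cl = true; return; }
  if (p <= 0.0) { cl = (p < 0.0); p = 0.0; }
  if (p >= n - 1.0) { cl = cl || (p > n - 1.0); p = n - 1.0; }
  a0 = (int)std::floor(p);
  if (a0 > n - 2) a0 = n - 2;
  a1 = a0 + 1;
  f = p - a0;
}

static inline Cell locate_cell(int i, int j, int k, const double* dp,
                               int m, int M, int nx, int ny, int nz) {
  Cell c;
  locate(i + dp[m], nx, c.i0, c.i1, c.fx, c.cx);
  locate(j + dp[m + M], ny, c.j0, c.j1, c.fy, c.cy);
  locate(k + dp[m + 2 * (size_t)M], nz, c.k0, c.k1, c.fz, c.cz);
  return c;
}

// Trilinear sampling of a multi-channel volume at p + disp(p), clamped to
// the grid. src: (nx,ny,nz,C); disp: (nx,ny,nz,3) in voxel units.
// [[Rcpp::export]]
NumericVector cpp_trilerp_fwd(NumericVector src, IntegerVector dim,
                              NumericVector disp) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], C = dim[3];
  const int M = nx * ny * nz;
  NumericVector out((size_t)M * C);
  out.attr("dim") = dim;
  const double* sp = REAL(src);
  const double* dp = REAL(disp);
  double* op = REAL(out);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const int m = idx3(i, j, k, nx, ny);
        const Cell c = locate_cell(i, j, k, dp, m, M, nx, ny, nz);
        const double wx0 = 1.0 - c.fx, wx1 = c.fx;
        const double wy0 = 1.0 - c.fy, wy1 = c.fy;
        const double wz0 = 1.0 - c.fz, wz1 = c.fz;
        const int i000 = idx3(c.i0, c.j0, c.k0, nx, ny);
        const int i100 = idx3(c.i1, c.j0, c.k0, nx, ny);
        const int i010 = idx3(c.i0, c.j1, c.k0, nx, ny);
        const int i110 = idx3(c.i1, c.j1, c.k0, nx, ny);
        const int i001 = idx3(c.i0, c.j0, c.k1, nx, ny);
        const int i101 = idx3(c.i1, c.j0, c.k1, nx, ny);
        const int i011 = idx3(c.i0, c.j1, c.k1, nx, ny);
        const int i111 = idx3(c.i1, c.j1, c.k1, nx, ny);
        for (int ch = 0; ch < C; ++ch) {
          const double* s = sp + (size_t)ch * M;
          op[m + (size_t)ch * M] =
            wz0 * (wy0 * (wx0 * s[i000] + wx1 * s[i100]) +
                   wy1 * (wx0 * s[i010] + wx1 * s[i110])) +
            wz1 * (wy0 * (wx0 * s[i001] + wx1 * s[i101]) +
                   wy1 * (wx0 * s[i011] + wx1 * s[i111]));
        }
      }
    }
  }
  return out;
}

// Gradients of the trilinear sample w.r.t. both the source volume and the
// displacement. Returns list(dsrc, ddisp). Clamped coordinates get zero
// displacement derivative (subgradient of the clamp).
// [[Rcpp::export]]
List cpp_trilerp_bwd(NumericVector src, IntegerVector dim,
                     NumericVector disp, NumericVector gout) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], C = dim[3];
  const int M = nx * ny * nz;
  NumericVector dsrc((size_t)M * C);
  dsrc.attr("dim") = dim;
  NumericVector ddisp((size_t)M * 3);
  ddisp.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  const double* sp = REAL(src);
  const double* dp = REAL(disp);
  const double* gp = REAL(gout);
  double* dsp = REAL(dsrc);
  double* ddp = REAL(ddisp);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const int m = idx3(i, j, k, nx, ny);
        const Cell c = locate_cell(i, j, k, dp, m, M, nx, ny, nz);
        const double wx0 = 1.0 - c.fx, wx1 = c.fx;
        const double wy0 = 1.0 - c.fy, wy1 = c.fy;
        const double wz0 = 1.0 - c.fz, wz1 = c.fz;
        const int i000 = idx3(c.i0, c.j0, c.k0, nx, ny);
        const int i100 = idx3(c.i1, c.j0, c.k0, nx, ny);
        const int i010 = idx3(c.i0, c.j1, c.k0, nx, ny);
        const int i110 = idx3(c.i1, c.j1, c.k0, nx, ny);
        const int i001 = idx3(c.i0, c.j0, c.k1, nx, ny);
        const int i101 = idx3(c.i1, c.j0, c.k1, nx, ny);
        const int i011 = idx3(c.i0, c.j1, c.k1, nx, ny);
        const int i111 = idx3(c.i1, c.j1, c.k1, nx, ny);
        double ax = 0.0, ay = 0.0, az = 0.0;
        for (int ch = 0; ch < C; ++ch) {
          const double* s = sp + (size_t)ch * M;
          double* ds = dsp + (size_t)ch * M;
          const double g = gp[m + (size_t)ch * M];
          if (g == 0.0) continue;
          ds[i000] += g * wx0 * wy0 * wz0;
          ds[i100] += g * wx1 * wy0 * wz0;
          ds[i010] += g * wx0 * wy1 * wz0;
          ds[i110] += g * wx1 * wy1 * wz0;
          ds[i001] += g * wx0 * wy0 * wz1;
          ds[i101] += g * wx1 * wy0 * wz1;
          ds[i011] += g * wx0 * wy1 * wz1;
          ds[i111] += g * wx1 * wy1 * wz1;
          ax += g * (wz0 * (wy0 * (s[i100] - s[i000]) + wy1 * (s[i110] - s[i010])) +
                     wz1 * (wy0 * (s[i101] - s[i001]) + wy1 * (s[i111] - s[i011])));
          ay += g * (wz0 * (wx0 * (s[i010] - s[i000]) + wx1 * (s[i110] - s[i100])) +
                     wz1 * (wx0 * (s[i011] - s[i001]) + wx1 * (s[i111] - s[i101])));
          az += g * (wy0 * (wx0 * (s[i001] - s[i000]) + wx1 * (s[i101] - s[i100])) +
                     wy1 * (wx0 * (s[i011] - s[i010]) + wx1 * (s[i111] - s[i110])));
        }
        if (!c.cx) ddp[m] = ax;
        if (!c.cy) ddp[m + M] = ay;
        if (!c.cz) ddp[m + 2 * (size_t)M] = az;
      }
    }
  }
  return List::create(_["dsrc"] = dsrc, _["ddisp"] = ddisp);
}

// 2x max pooling; returns pooled volume plus 0-based argmax indices into
// the input (per pooled cell), needed for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], C = dim[3];
  const int M = nx * ny * nz;
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const int Mo = ox * oy * oz;
  NumericVector out((size_t)Mo * C);
  out.attr("dim") = IntegerVector::create(ox, oy, oz, C);
  IntegerVector amax((size_t)Mo * C);
  const double* xp = REAL(x);
  double* op = REAL(out);
  int* ap = INTEGER(amax);
  for (int ch = 0; ch < C; ++ch) {
    const double* xc = xp + (size_t)ch * M;
    for (int k = 0; k < oz; ++k) {
      for (int j = 0; j < oy; ++j) {
        for (int i = 0; i < ox; ++i) {
          double best = -1e300;
          int besti = 0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                const int t = idx3(2 * i + di, 2 * j + dj, 2 * k + dk, nx, ny);
                if (xc[t] > best) { best = xc[t]; besti = t; }
              }
          const size_t o = idx3(i, j, k, ox, oy) + (size_t)ch * Mo;
          op[o] = best;
          ap[o] = besti + ch * M;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector g, IntegerVector amax,
                               IntegerVector dim_in) {
  NumericVector dx((size_t)dim_in[0] * dim_in[1] * dim_in[2] * dim_in[3]);
  dx.attr("dim") = dim_in;
  double* dp = REAL(dx);
  const double* gp = REAL(g);
  const int* ap = INTEGER(amax);
  const R_xlen_t n = amax.size();
  for (R_xlen_t t = 0; t < n; ++t) dp[ap[t]] += gp[t];
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2(NumericVector x, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], C = dim[3];
  const int M = nx * ny * nz;
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  const int Mo = ox * oy * oz;
  NumericVector out((size_t)Mo * C);
  out.attr("dim") = IntegerVector::create(ox, oy, oz, C);
  const double* xp = REAL(x);
  double* op = REAL(out);
  for (int ch = 0; ch < C; ++ch) {
    const double* xc = xp + (size_t)ch * M;
    double* oc = op + (size_t)ch * Mo;
    for (int k = 0; k < oz; ++k)
      for (int j = 0; j < oy; ++j)
        for (int i = 0; i < ox; ++i)
          oc[idx3(i, j, k, ox, oy)] = xc[idx3(i / 2, j / 2, k / 2, nx, ny)];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector g, IntegerVector dim_in) {
  const int nx = dim_in[0], ny = dim_in[1], nz = dim_in[2], C = dim_in[3];
  const int M = nx * ny * nz;
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  const int Mo = ox * oy * oz;
  NumericVector dx((size_t)M * C);
  dx.attr("dim") = dim_in;
  const double* gp = REAL(g);
  double* dp = REAL(dx);
  for (int ch = 0; ch < C; ++ch) {
    const double* gc = gp + (size_t)ch * Mo;
    double* dc = dp + (size_t)ch * M;
    for (int k = 0; k < oz; ++k)
      for (int j = 0; j < oy; ++j)
        for (int i = 0; i < ox; ++i)
          dc[idx3(i / 2, j / 2, k / 2, nx, ny)] += gc[idx3(i, j, k, ox, oy)];
  }
  return dx;
}

// Separable sliding-window sum with zero padding, window n (odd), applied
// along all three axes of a single-channel volume.
// [[Rcpp::export]]
NumericVector cpp_boxsum(NumericVector x, IntegerVector dim, int n) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int h = n / 2;
  NumericVector a = clone(x);
  NumericVector b((size_t)nx * ny * nz);
  b.attr("dim") = dim;
  a.attr("dim") = dim;
  double* ap = REAL(a);
  double* bp = REAL(b);
  // x axis
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const size_t off = (size_t)nx * (j + (size_t)ny * k);
      double s = 0.0;
      for (int i = 0; i < std::min(h, nx); ++i) s += ap[off + i];
      for (int i = 0; i < nx; ++i) {
        if (i + h < nx) s += ap[off + i + h];
        bp[off + i] = s;
        if (i - h >= 0) s -= ap[off + i - h];
      }
    }
  // y axis
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      const size_t base = i + (size_t)nx * ny * k;
      double s = 0.0;
      for (int j = 0; j < std::min(h, ny); ++j) s += bp[base + (size_t)nx * j];
      for (int j = 0; j < ny; ++j) {
        if (j + h < ny) s += bp[base + (size_t)nx * (j + h)];
        ap[base + (size_t)nx * j] = s;
        if (j - h >= 0) s -= bp[base + (size_t)nx * (j - h)];
      }
    }
  // z axis
  const size_t stride = (size_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const size_t base = i + (size_t)nx * j;
      double s = 0.0;
      for (int k = 0; k < std::min(h, nz); ++k) s += ap[base + stride * k];
      for (int k = 0; k < nz; ++k) {
        if (k + h < nz) s += ap[base + stride * (k + h)];
        bp[base + stride * k] = s;
        if (k - h >= 0) s -= ap[base + stride * (k - h)];
      }
    }
  return b;
}

// Group normalisation over a channel-last volume: each of `groups`
// channel blocks is normalised by its mean/variance over all voxels and
// block channels, then scaled/shifted per channel.
// [[Rcpp::export]]
List cpp_gn_fwd(NumericVector x, IntegerVector dim, NumericVector gamma,
                NumericVector beta, int groups, double eps) {
  const int C = dim[3];
  const R_xlen_t M = (R_xlen_t)dim[0] * dim[1] * dim[2];
  const int cg = C / groups;
  NumericVector out(x.size());
  out.attr("dim") = dim;
  NumericVector xhat(x.size());
  NumericVector istd(groups);
  const double* xp = REAL(x);
  double* op = REAL(out);
  double* hp = REAL(xhat);
  for (int g = 0; g < groups; ++g) {
    const double* xg = xp + (R_xlen_t)g * cg * M;
    const R_xlen_t n = (R_xlen_t)cg * M;
    double s = 0.0, s2 = 0.0;
    for (R_xlen_t t = 0; t < n; ++t) { s += xg[t]; s2 += xg[t] * xg[t]; }
    const double mu = s / n;
    const double var = s2 / n - mu * mu;
    const double is = 1.0 / std::sqrt(var + eps);
    istd[g] = is;
    for (int c = 0; c < cg; ++c) {
      const double ga = gamma[g * cg + c], be = beta[g * cg + c];
      const double* xc = xg + (R_xlen_t)c * M;
      double* hc = hp + ((R_xlen_t)g * cg + c) * M;
      double* oc = op + ((R_xlen_t)g * cg + c) * M;
      for (R_xlen_t t = 0; t < M; ++t) {
        const double h = (xc[t] - mu) * is;
        hc[t] = h;
        oc[t] = ga * h + be;
      }
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["istd"] = istd);
}

// [[Rcpp::export]]
List cpp_gn_bwd(NumericVector gout, IntegerVector dim, NumericVector xhat,
                NumericVector istd, NumericVector gamma, int groups) {
  const int C = dim[3];
  const R_xlen_t M = (R_xlen_t)dim[0] * dim[1] * dim[2];
  const int cg = C / groups;
  NumericVector dx(gout.size());
  dx.attr("dim") = dim;
  NumericVector dgamma(C), dbeta(C);
  const double* gp = REAL(gout);
  const double* hp = REAL(xhat);
  double* dp = REAL(dx);
  for (int g = 0; g < groups; ++g) {
    const R_xlen_t off = (R_xlen_t)g * cg * M;
    const R_xlen_t n = (R_xlen_t)cg * M;
    double sh = 0.0, shh = 0.0;
    for (int c = 0; c < cg; ++c) {
      const double ga = gamma[g * cg + c];
      const double* gc = gp + off + (R_xlen_t)c * M;
      const double* hc = hp + off + (R_xlen_t)c * M;
      double dg = 0.0, db = 0.0;
      for (R_xlen_t t = 0; t < M; ++t) {
        dg += gc[t] * hc[t];
        db += gc[t];
        sh += ga * gc[t];
        shh += ga * gc[t] * hc[t];
      }
      dgamma[g * cg + c] = dg;
      dbeta[g * cg + c] = db;
    }
    const double mh = sh / n, mhh = shh / n;
    for (int c = 0; c < cg; ++c) {
      const double ga = gamma[g * cg + c];
      const double* gc = gp + off + (R_xlen_t)c * M;
      const double* hc = hp + off + (R_xlen_t)c * M;
      double* dc = dp + off + (R_xlen_t)c * M;
      for (R_xlen_t t = 0; t < M; ++t)
        dc[t] = istd[g] * (ga * gc[t] - mh - hc[t] * mhh);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Spatial gradient penalty of a displacement field: mean over voxels of
// the Frobenius norm of the forward-difference Jacobian (zero-padded
// last slice). Returns the value and the per-voxel norm (for backward).
// [[Rcpp::export]]
List cpp_gp_fwd(NumericVector u, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t M = (R_xlen_t)nx * ny * nz;
  NumericVector nrm(M);
  const double* up = REAL(u);
  double* np = REAL(nrm);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t m = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        double s2 = 0.0;
        for (int c = 0; c < 3; ++c) {
          const double* uc = up + (R_xlen_t)c * M;
          const double v = uc[m];
          if (i + 1 < nx) { const double d = uc[m + 1] - v; s2 += d * d; }
          if (j + 1 < ny) { const double d = uc[m + nx] - v; s2 += d * d; }
          if (k + 1 < nz) { const double d = uc[m + (R_xlen_t)nx * ny] - v; s2 += d * d; }
        }
        np[m] = std::sqrt(s2);
      }
  double val = 0.0;
  for (R_xlen_t m = 0; m < M; ++m) val += np[m];
  return List::create(_["value"] = val / M, _["nrm"] = nrm);
}

// [[Rcpp::export]]
NumericVector cpp_gp_bwd(NumericVector u, IntegerVector dim,
                         NumericVector nrm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t M = (R_xlen_t)nx * ny * nz;
  NumericVector du(u.size());
  du.attr("dim") = dim;
  const double* up = REAL(u);
  const double* np = REAL(nrm);
  double* dp = REAL(du);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t m = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        const double w = 1.0 / (M * std::max(np[m], 1e-12));
        for (int c = 0; c < 3; ++c) {
          const double* uc = up + (R_xlen_t)c * M;
          double* dc = dp + (R_xlen_t)c * M;
          const double v = uc[m];
          if (i + 1 < nx) {
            const double d = (uc[m + 1] - v) * w;
            dc[m + 1] += d; dc[m] -= d;
          }
          if (j + 1 < ny) {
            const double d = (uc[m + nx] - v) * w;
            dc[m + nx] += d; dc[m] -= d;
          }
          if (k + 1 < nz) {
            const double d = (uc[m + (R_xlen_t)nx * ny] - v) * w;
            dc[m + (R_xlen_t)nx * ny] += d; dc[m] -= d;
          }
        }
      }
  return du;
}
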