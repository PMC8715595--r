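// Low-level numerical kernels for displacement-field prediction and warping.
//
// Feature maps are stored as (nvox x channels) matrices whose row index is the
// linear voxel index of an (nx, ny, nz) grid in column-major (R array) order:
// v = x + nx*(y + ny*z), 0-based. All convolutions are stride-1, zero-padded
// "same"; image sampling clamps to the border (replicate edge).

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::uword;

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// ---------------------------------------------------------------- im2col ----

static arma::mat im2col(const arma::mat& X, const arma::ivec& n,
                        const arma::ivec& k, const arma::ivec& dil) {
  const int nx = n[0], ny = n[1], nz = n[2];
  const int kx = k[0], ky = k[1], kz = k[2];
  const int cin = X.n_cols;
  const int kvol = kx * ky * kz;
  const int nvox = nx * ny * nz;
  arma::mat col(static_cast<uword>(kvol) * cin, nvox, arma::fill::zeros);

  for (int c = 0; c < cin; ++c) {
    const double* xc = X.colptr(c);
    for (int oz = 0; oz < kz; ++oz) {
      const int dz = (oz - (kz - 1) / 2) * dil[2];
      for (int oy = 0; oy < ky; ++oy) {
        const int dy = (oy - (ky - 1) / 2) * dil[1];
        for (int ox = 0; ox < kx; ++ox) {
          const int dx = (ox - (kx - 1) / 2) * dil[0];
          const int row = ox + kx * (oy + ky * oz) + kvol * c;
          for (int z = 0; z < nz; ++z) {
            const int sz = z + dz;
            if (sz < 0 || sz >= nz) continue;
            for (int y = 0; y < ny; ++y) {
              const int sy = y + dy;
              if (sy < 0 || sy >= ny) continue;
              const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
              const int vbase = nx * (y + ny * z);
              const int sbase = nx * (sy + ny * sz) + dx;
              for (int x = x0; x < x1; ++x)
                col(row, vbase + x) = xc[sbase + x];
            }
          }
        }
      }
    }
  }
  return col;
}

static void col2im_add(arma::mat& dX, const arma::mat& dcol,
                       const arma::ivec& n, const arma::ivec& k,
                       const arma::ivec& dil) {
  const int nx = n[0], ny = n[1], nz = n[2];
  const int kx = k[0], ky = k[1], kz = k[2];
  const int cin = dX.n_cols;
  const int kvol = kx * ky * kz;

  for (int c = 0; c < cin; ++c) {
    double* xc = dX.colptr(c);
    for (int oz = 0; oz < kz; ++oz) {
      const int dz = (oz - (kz - 1) / 2) * dil[2];
      for (int oy = 0; oy < ky; ++oy) {
        const int dy = (oy - (ky - 1) / 2) * dil[1];
        for (int ox = 0; ox < kx; ++ox) {
          const int dx = (ox - (kx - 1) / 2) * dil[0];
          const int row = ox + kx * (oy + ky * oz) + kvol * c;
          for (int z = 0; z < nz; ++z) {
            const int sz = z + dz;
            if (sz < 0 || sz >= nz) continue;
            for (int y = 0; y < ny; ++y) {
              const int sy = y + dy;
              if (sy < 0 || sy >= ny) continue;
              const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
              const int vbase = nx * (y + ny * z);
              const int sbase = nx * (sy + ny * sz) + dx;
              for (int x = x0; x < x1; ++x)
                xc[sbase + x] += dcol(row, vbase + x);
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_conv_fwd(const arma::mat& X, const arma::ivec& n,
                  const arma::mat& W, const arma::vec& b,
                  const arma::ivec& k, const arma::ivec& dil,
                  bool keep_col) {
  arma::mat col = im2col(X, n, k, dil);       // (kvol*cin) x nvox
  arma::mat Y = col.t() * W;                  // nvox x cout
  Y.each_row() += b.t();
  if (keep_col)
    return List::create(_["Y"] = Y, _["col"] = col);
  return List::create(_["Y"] = Y);
}

// Backward pass reusing the cached col matrix from the forward pass.
// [[Rcpp::export]]
List cpp_conv_bwd(const arma::mat& col, const arma::ivec& n, int cin,
                  const arma::mat& W, const arma::mat& dY,
                  const arma::ivec& k, const arma::ivec& dil) {
  arma::mat dW = col * dY;                    // (kvol*cin) x cout
  arma::vec db = arma::sum(dY, 0).t();
  arma::mat dcol = W * dY.t();                // (kvol*cin) x nvox
  arma::mat dX(col.n_cols, cin, arma::fill::zeros);
  col2im_add(dX, dcol, n, k, dil);
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// ------------------------------------------------------------- pooling ------

// [[Rcpp::export]]
List cpp_maxpool_fwd(const arma::mat& X, const arma::ivec& n,
                     const arma::ivec& f) {
  const int nx = n[0], ny = n[1], nz = n[2];
  const int fx = f[0], fy = f[1], fz = f[2];
  const int mx = nx / fx, my = ny / fy, mz = nz / fz;
  const int C = X.n_cols, nout = mx * my * mz;
  arma::mat Y(nout, C);
  arma::umat idx(nout, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    for (int z = 0; z < mz; ++z)
      for (int y = 0; y < my; ++y)
        for (int x = 0; x < mx; ++x) {
          double best = -std::numeric_limits<double>::infinity();
          int bidx = 0;
          for (int oz = 0; oz < fz; ++oz)
            for (int oy = 0; oy < fy; ++oy)
              for (int ox = 0; ox < fx; ++ox) {
                const int v = (x * fx + ox) +
                  nx * ((y * fy + oy) + ny * (z * fz + oz));
                if (xc[v] > best) { best = xc[v]; bidx = v; }
              }
          const int vo = x + mx * (y + my * z);
          Y(vo, c) = best;
          idx(vo, c) = bidx;
        }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool_bwd(const arma::umat& idx, int nvox_in,
                          const arma::mat& dY) {
  arma::mat dX(nvox_in, dY.n_cols, arma::fill::zeros);
  for (uword c = 0; c < dY.n_cols; ++c)
    for (uword v = 0; v < dY.n_rows; ++v)
      dX(idx(v, c), c) += dY(v, c);
  return dX;
}

// ---------------------------------------------------------- upsampling ------

// [[Rcpp::export]]
arma::mat cpp_upsample_fwd(const arma::mat& X, const arma::ivec& n,
                           const arma::ivec& f) {
  const int nx = n[0], ny = n[1], nz = n[2];
  const int fx = f[0], fy = f[1], fz = f[2];
  const int mx = nx * fx, my = ny * fy, mz = nz * fz;
  const int C = X.n_cols;
  arma::mat Y(static_cast<uword>(mx) * my * mz, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    double* yc = Y.colptr(c);
    for (int z = 0; z < mz; ++z)
      for (int y = 0; y < my; ++y) {
        const int sbase = nx * ((y / fy) + ny * (z / fz));
        const int vbase = mx * (y + my * z);
        for (int x = 0; x < mx; ++x)
          yc[vbase + x] = xc[sbase + x / fx];
      }
  }
  return Y;
}

// [[Rcpp::export]]
arma::mat cpp_upsample_bwd(const arma::mat& dY, const arma::ivec& n,
                           const arma::ivec& f) {
  // n is the *input* (coarse) grid; dY lives on the fine grid.
  const int nx = n[0], ny = n[1], nz = n[2];
  const int fx = f[0], fy = f[1], fz = f[2];
  const int mx = nx * fx, my = ny * fy, mz = nz * fz;
  const int C = dY.n_cols;
  arma::mat dX(static_cast<uword>(nx) * ny * nz, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* gc = dY.colptr(c);
    double* xc = dX.colptr(c);
    for (int z = 0; z < mz; ++z)
      for (int y = 0; y < my; ++y) {
        const int sbase = nx * ((y / fy) + ny * (z / fz));
        const int vbase = mx * (y + my * z);
        for (int x = 0; x < mx; ++x)
          xc[sbase + x / fx] += gc[vbase + x];
      }
  }
  return dX;
}

// ------------------------------------------------- trilinear sampling -------

// Sample vol at one (possibly fractional) voxel coordinate, border-clamped.
// Optionally accumulate the spatial gradient of the interpolant.
static double sample_one(const double* vol, const int nx, const int ny,
                         const int nz, double px, double py, double pz,
                         double* grad) {
  // clamp the continuous coordinate into [0, n-1]
  px = px < 0 ? 0 : (px > nx - 1 ? nx - 1 : px);
  py = py < 0 ? 0 : (py > ny - 1 ? ny - 1 : py);
  pz = pz < 0 ? 0 : (pz > nz - 1 ? nz - 1 : pz);
  int x0 = static_cast<int>(std::floor(px));
  int y0 = static_cast<int>(std::floor(py));
  int z0 = static_cast<int>(std::floor(pz));
  if (x0 > nx - 2) x0 = std::max(0, nx - 2);
  if (y0 > ny - 2) y0 = std::max(0, ny - 2);
  if (z0 > nz - 2) z0 = std::max(0, nz - 2);
  const int x1 = std::min(x0 + 1, nx - 1);
  const int y1 = std::min(y0 + 1, ny - 1);
  const int z1 = std::min(z0 + 1, nz - 1);
  const double tx = px - x0, ty = py - y0, tz = pz - z0;

  const double v000 = vol[x0 + nx * (y0 + ny * z0)];
  const double v100 = vol[x1 + nx * (y0 + ny * z0)];
  const double v010 = vol[x0 + nx * (y1 + ny * z0)];
  const double v110 = vol[x1 + nx * (y1 + ny * z0)];
  const double v001 = vol[x0 + nx * (y0 + ny * z1)];
  const double v101 = vol[x1 + nx * (y0 + ny * z1)];
  const double v011 = vol[x0 + nx * (y1 + ny * z1)];
  const double v111 = vol[x1 + nx * (y1 + ny * z1)];

  const double c00 = v000 * (1 - tx) + v100 * tx;
  const double c10 = v010 * (1 - tx) + v110 * tx;
  const double c01 = v001 * (1 - tx) + v101 * tx;
  const double c11 = v011 * (1 - tx) + v111 * tx;
  const double c0 = c00 * (1 - ty) + c10 * ty;
  const double c1 = c01 * (1 - ty) + c11 * ty;

  if (grad) {
    const double gx00 = v100 - v000, gx10 = v110 - v010;
    const double gx01 = v101 - v001, gx11 = v111 - v011;
    grad[0] = (gx00 * (1 - ty) + gx10 * ty) * (1 - tz) +
              (gx01 * (1 - ty) + gx11 * ty) * tz;
    grad[1] = (c10 - c00) * (1 - tz) + (c11 - c01) * tz;
    grad[2] = c1 - c0;
  }
  return c0 * (1 - tz) + c1 * tz;
}

// [[Rcpp::export]]
arma::vec cpp_sample_linear(const arma::vec& vol, const arma::ivec& n,
                            const arma::mat& pts) {
  const int nx = n[0], ny = n[1], nz = n[2];
  arma::vec out(pts.n_rows);
  for (uword i = 0; i < pts.n_rows; ++i)
    out[i] = sample_one(vol.memptr(), nx, ny, nz,
                        pts(i, 0), pts(i, 1), pts(i, 2), nullptr);
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_warp(const arma::vec& vol, const arma::ivec& n,
                   const arma::mat& field, bool nearest) {
  const int nx = n[0], ny = n[1], nz = n[2];
  const int nvox = nx * ny * nz;
  arma::vec out(nvox);
  const double* vp = vol.memptr();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int v = x + nx * (y + ny * z);
        const double px = x + field(v, 0);
        const double py = y + field(v, 1);
        const double pz = z + field(v, 2);
        if (nearest) {
          const int ix = clampi(static_cast<int>(std::lround(px)), 0, nx - 1);
          const int iy = clampi(static_cast<int>(std::lround(py)), 0, ny - 1);
          const int iz = clampi(static_cast<int>(std::lround(pz)), 0, nz - 1);
          out[v] = vp[ix + nx * (iy + ny * iz)];
        } else {
          out[v] = sample_one(vp, nx, ny, nz, px, py, pz, nullptr);
        }
      }
  return out;
}

// Gradient of sum(g * warp(vol, field)) with respect to the field.
// [[Rcpp::export]]
arma::mat cpp_warp_bwd_field(const arma::vec& vol, const arma::ivec& n,
                             const arma::mat& field, const arma::vec& g) {
  const int nx = n[0], ny = n[1], nz = n[2];
  const int nvox = nx * ny * nz;
  arma::mat dF(nvox, 3, arma::fill::zeros);
  const double* vp = vol.memptr();
  double grad[3];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int v = x + nx * (y + ny * z);
        if (g[v] == 0.0) continue;
        sample_one(vp, nx, ny, nz, x + field(v, 0), y + field(v, 1),
                   z + field(v, 2), grad);
        dF(v, 0) = g[v] * grad[0];
        dF(v, 1) = g[v] * grad[1];
        dF(v, 2) = g[v] * grad[2];
      }
  return dF;
}

// ------------------------------------- local squared-NCC similarity ---------

// Windowed squared normalized cross-correlation, averaged over all voxels
// and negated. Windows have half-width radius r per axis and replicate the
// border. Returns the loss and (optionally) its gradient wrt `pred`.
// [[Rcpp::export]]
List cpp_ncc_loss(const arma::vec& ref, const arma::vec& pred,
                  const arma::ivec& n, const arma::ivec& r, double eps,
                  bool want_grad) {
  const int nx = n[0], ny = n[1], nz = n[2];
  const int rx = r[0], ry = r[1], rz = r[2];
  const int nvox = nx * ny * nz;
  const double W = static_cast<double>((2 * rx + 1)) * (2 * ry + 1) *
                   (2 * rz + 1);

  arma::vec Sr(nvox, arma::fill::zeros), Sm(nvox, arma::fill::zeros);
  arma::vec Srr(nvox, arma::fill::zeros), Smm(nvox, arma::fill::zeros);
  arma::vec Srm(nvox, arma::fill::zeros);

  const double* rp = ref.memptr();
  const double* mp = pred.memptr();

  for (int oz = -rz; oz <= rz; ++oz)
    for (int oy = -ry; oy <= ry; ++oy)
      for (int ox = -rx; ox <= rx; ++ox)
        for (int z = 0; z < nz; ++z) {
          const int sz = clampi(z + oz, 0, nz - 1);
          for (int y = 0; y < ny; ++y) {
            const int sy = clampi(y + oy, 0, ny - 1);
            const int vb = nx * (y + ny * z);
            const int sb = nx * (sy + ny * sz);
            for (int x = 0; x < nx; ++x) {
              const int sx = clampi(x + ox, 0, nx - 1);
              const double rv = rp[sb + sx], mv = mp[sb + sx];
              const int v = vb + x;
              Sr[v] += rv;  Sm[v] += mv;
              Srr[v] += rv * rv; Smm[v] += mv * mv; Srm[v] += rv * mv;
            }
          }
        }

  arma::vec Cc(nvox), Vr(nvox), Vm(nvox), D(nvox);
  double loss = 0.0;
  for (int v = 0; v < nvox; ++v) {
    Cc[v] = Srm[v] - Sr[v] * Sm[v] / W;
    Vr[v] = Srr[v] - Sr[v] * Sr[v] / W;
    Vm[v] = Smm[v] - Sm[v] * Sm[v] / W;
    D[v] = Vr[v] * Vm[v] + eps;
    loss += Cc[v] * Cc[v] / D[v];
  }
  loss = -loss / nvox;

  if (!want_grad)
    return List::create(_["loss"] = loss);

  // per-center coefficients
  arma::vec a(nvox), bcoef(nvox), rbar(nvox), mbar(nvox);
  for (int v = 0; v < nvox; ++v) {
    a[v] = 2.0 * Cc[v] / D[v];
    bcoef[v] = 2.0 * Cc[v] * Cc[v] * Vr[v] / (D[v] * D[v]);
    rbar[v] = Sr[v] / W;
    mbar[v] = Sm[v] / W;
  }

  arma::vec grad(nvox, arma::fill::zeros);
  for (int oz = -rz; oz <= rz; ++oz)
    for (int oy = -ry; oy <= ry; ++oy)
      for (int ox = -rx; ox <= rx; ++ox)
        for (int z = 0; z < nz; ++z) {
          const int sz = clampi(z + oz, 0, nz - 1);
          for (int y = 0; y < ny; ++y) {
            const int sy = clampi(y + oy, 0, ny - 1);
            const int vb = nx * (y + ny * z);
            const int sb = nx * (sy + ny * sz);
            for (int x = 0; x < nx; ++x) {
              const int sx = clampi(x + ox, 0, nx - 1);
              const int v = vb + x;       // window center
              const int q = sb + sx;      // clamped sample position
              grad[q] += a[v] * (rp[q] - rbar[v]) -
                         bcoef[v] * (mp[q] - mbar[v]);
            }
          }
        }
  grad *= -1.0 / nvox;
  return List::create(_["loss"] = loss, _["grad"] = grad);
}

// -------------------------------------------------- Gaussian smoothing ------

// Separable Gaussian filter, replicate-edge borders; sigma in voxels per axis.
// [[Rcpp::export]]
arma::vec cpp_gauss_smooth(const arma::vec& vol, const arma::ivec& n,
                           const arma::vec& sigma) {
  const int dims[3] = {static_cast<int>(n[0]), static_cast<int>(n[1]),
                       static_cast<int>(n[2])};
  arma::vec cur = vol;
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma[ax];
    if (s <= 0 || dims[ax] == 1) continue;
    const int rad = std::max(1, static_cast<int>(std::ceil(3.0 * s)));
    arma::vec kern(2 * rad + 1);
    for (int i = -rad; i <= rad; ++i)
      kern[i + rad] = std::exp(-0.5 * i * i / (s * s));
    kern /= arma::accu(kern);

    arma::vec out(cur.n_elem, arma::fill::zeros);
    const int strides[3] = {1, nx, nx * ny};
    const int st = strides[ax];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int pos[3] = {x, y, z};
          const int v = x + nx * (y + ny * z);
          double acc = 0;
          for (int i = -rad; i <= rad; ++i) {
            const int pc = clampi(pos[ax] + i, 0, dims[ax] - 1);
            acc += kern[i + rad] * cur[v + (pc - pos[ax]) * st];
          }
          out[v] = acc;
        }
    cur = out;
  }
  return cur;
}

// --------------------------------------------- binary morphology / CC -------

// 6-connected dilation (iterated `iter` times); erosion via complement.
// [[Rcpp::export]]
arma::ivec cpp_dilate6(const arma::ivec& mask, const arma::ivec& n, int iter) {
  const int nx = n[0], ny = n[1], nz = n[2];
  arma::ivec cur = mask;
  for (int it = 0; it < iter; ++it) {
    arma::ivec out = cur;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int v = x + nx * (y + ny * z);
          if (cur[v]) continue;
          bool hit = false;
          if (x > 0 && cur[v - 1]) hit = true;
          else if (x < nx - 1 && cur[v + 1]) hit = true;
          else if (y > 0 && cur[v - nx]) hit = true;
          else if (y < ny - 1 && cur[v + nx]) hit = true;
          else if (z > 0 && cur[v - nx * ny]) hit = true;
          else if (z < nz - 1 && cur[v + nx * ny]) hit = true;
          if (hit) out[v] = 1;
        }
    cur = out;
  }
  return cur;
}

// Label 6-connected components of a binary grid; labels 1..K, background 0.
// [[Rcpp::export]]
arma::ivec cpp_label_cc6(const arma::ivec& mask, const arma::ivec& n) {
  const int nx = n[0], ny = n[1], nz = n[2];
  const int nvox = nx * ny * nz;
  arma::ivec lab(nvox, arma::fill::zeros);
  int next = 0;
  std::queue<int> q;
  for (int seed = 0; seed < nvox; ++seed) {
    if (!mask[seed] || lab[seed]) continue;
    lab[seed] = ++next;
    q.push(seed);
    while (!q.empty()) {
      const int v = q.front(); q.pop();
      const int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      const int nb[6] = {x > 0 ? v - 1 : -1, x < nx - 1 ? v + 1 : -1,
                         y > 0 ? v - nx : -1, y < ny - 1 ? v + nx : -1,
                         z > 0 ? v - nx * ny : -1,
                         z < nz - 1 ? v + nx * ny : -1};
      for (int i = 0; i < 6; ++i)
        if (nb[i] >= 0 && mask[nb[i]] && !lab[nb[i]]) {
          lab[nb[i]] = next;
          q.push(nb[i]);
        }
    }
  }
  return lab;
}
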