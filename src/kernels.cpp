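// Dense 3D network and resampling kernels.
//
// Layout conventions (match R's column-major arrays):
//   volume:      dim (nx, ny, nz), linear index x + nx*(y + ny*z)
//   feature map: dim (nx, ny, nz, C), channel slowest
//   conv weight: dim (k, k, k, Cin, Cout)
// im2col patch column r = kx + k*ky + k^2*kz + k^3*ci, so the column matrix
// multiplies the weight array reshaped to (k^3*Cin, Cout) directly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int floordiv_out(int n, int pad, int k, int stride) {
  return (n + 2 * pad - k) / stride + 1;
}

// ---------------------------------------------------------------- sampling

// Trilinear interpolation of vol at continuous voxel coordinates (0-based,
// voxel centers at integer indices). Out-of-grid samples return `fill`.
// [[Rcpp::export(name = ".cpp_sample_trilinear")]]
NumericVector cpp_sample_trilinear(NumericVector vol, IntegerVector dims,
                                   NumericMatrix coords, double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = coords.nrow();
  NumericVector out(n);
  const double *v = vol.begin();
  for (int i = 0; i < n; ++i) {
    double cx = coords(i, 0), cy = coords(i, 1), cz = coords(i, 2);
    if (!(cx > -1.0 && cx < nx && cy > -1.0 && cy < ny &&
          cz > -1.0 && cz < nz)) { // fully outside support
      out[i] = fill;
      continue;
    }
    int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy),
        z0 = (int)std::floor(cz);
    double fx = cx - x0, fy = cy - y0, fz = cz - z0;
    double acc = 0.0;
    for (int dz = 0; dz < 2; ++dz) {
      int z = z0 + dz;
      double wz = dz ? fz : 1.0 - fz;
      if (wz == 0.0) continue;
      for (int dy = 0; dy < 2; ++dy) {
        int y = y0 + dy;
        double wy = dy ? fy : 1.0 - fy;
        if (wy == 0.0) continue;
        for (int dx = 0; dx < 2; ++dx) {
          int x = x0 + dx;
          double wx = dx ? fx : 1.0 - fx;
          if (wx == 0.0) continue;
          double val;
          if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
            val = fill;
          else
            val = v[x + (size_t)nx * (y + (size_t)ny * z)];
          acc += wx * wy * wz * val;
        }
      }
    }
    out[i] = acc;
  }
  return out;
}

// ------------------------------------------------------------- convolution

// valid output range [lo, hi) along one axis for kernel offset ko:
// input index i = o*stride - pad + ko must lie in [0, n)
static inline void valid_range(int n, int no, int stride, int pad, int ko,
                               int &lo, int &hi) {
  lo = (pad - ko + stride - 1) / stride;
  if (lo < 0) lo = 0;
  hi = (n - 1 + pad - ko) / stride + 1;
  if (hi > no) hi = no;
  if (hi < lo) hi = lo;
}

static arma::mat im2col(const double *x, int nx, int ny, int nz, int cin,
                        int k, int stride, int pad,
                        int ox, int oy, int oz) {
  const size_t nvox = (size_t)ox * oy * oz;
  if (k == 1 && stride == 1 && pad == 0) // pure channel mixing: a reshape
    return arma::mat(const_cast<double *>(x), nvox, cin, true, true);
  arma::mat col(nvox, (size_t)k * k * k * cin, arma::fill::zeros);
  for (int ci = 0; ci < cin; ++ci) {
    const double *xc = x + (size_t)ci * nx * ny * nz;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const size_t pcol = (size_t)kx + k * (ky + (size_t)k * kz) +
                              (size_t)k * k * k * ci;
          double *dst = col.colptr(pcol);
          int zlo, zhi, ylo, yhi, xlo, xhi;
          valid_range(nz, oz, stride, pad, kz, zlo, zhi);
          valid_range(ny, oy, stride, pad, ky, ylo, yhi);
          valid_range(nx, ox, stride, pad, kx, xlo, xhi);
          for (int z = zlo; z < zhi; ++z) {
            const int iz = z * stride - pad + kz;
            for (int y = ylo; y < yhi; ++y) {
              const int iy = y * stride - pad + ky;
              const double *src = xc + (size_t)nx * (iy + (size_t)ny * iz)
                                  - pad + kx;
              double *d = dst + (size_t)ox * (y + (size_t)oy * z);
              if (stride == 1) {
                for (int xo = xlo; xo < xhi; ++xo) d[xo] = src[xo];
              } else {
                for (int xo = xlo; xo < xhi; ++xo)
                  d[xo] = src[(size_t)xo * stride];
              }
            }
          }
        }
  }
  return col;
}

// [[Rcpp::export(name = ".cpp_conv3d_forward")]]
List cpp_conv3d_forward(NumericVector x, IntegerVector xdim,
                        NumericVector w, NumericVector b,
                        int k, int stride, int pad, bool keep_col) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], cin = xdim[3];
  const int cout = b.size();
  const int ox = floordiv_out(nx, pad, k, stride);
  const int oy = floordiv_out(ny, pad, k, stride);
  const int oz = floordiv_out(nz, pad, k, stride);
  arma::mat col = im2col(x.begin(), nx, ny, nz, cin, k, stride, pad,
                         ox, oy, oz);
  arma::mat W(w.begin(), (size_t)k * k * k * cin, cout, false, true);
  arma::mat out = col * W;
  out.each_row() += arma::rowvec(b.begin(), cout, false, true);
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(ox, oy, oz, cout);
  List ret = List::create(_["out"] = res);
  if (keep_col) ret["col"] = wrap(col);
  return ret;
}

// [[Rcpp::export(name = ".cpp_conv3d_backward")]]
List cpp_conv3d_backward(NumericMatrix colR, NumericVector w,
                         IntegerVector xdim, NumericVector gout,
                         IntegerVector odim, int k, int stride, int pad) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], cin = xdim[3];
  const int ox = odim[0], oy = odim[1], oz = odim[2], cout = odim[3];
  const size_t nvox = (size_t)ox * oy * oz;
  arma::mat col(colR.begin(), nvox, (size_t)k * k * k * cin, false, true);
  arma::mat G(gout.begin(), nvox, cout, false, true);
  arma::mat W(w.begin(), (size_t)k * k * k * cin, cout, false, true);

  arma::mat gW = col.t() * G;
  arma::rowvec gB = arma::sum(G, 0);
  arma::mat gCol = G * W.t();

  // col2im: scatter-add gradient back onto the input grid
  NumericVector gX((size_t)nx * ny * nz * cin);
  double *gx = gX.begin();
  for (int ci = 0; ci < cin; ++ci) {
    double *gxc = gx + (size_t)ci * nx * ny * nz;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const size_t pcol = (size_t)kx + k * (ky + (size_t)k * kz) +
                              (size_t)k * k * k * ci;
          const double *src = gCol.colptr(pcol);
          int zlo, zhi, ylo, yhi, xlo, xhi;
          valid_range(nz, oz, stride, pad, kz, zlo, zhi);
          valid_range(ny, oy, stride, pad, ky, ylo, yhi);
          valid_range(nx, ox, stride, pad, kx, xlo, xhi);
          for (int z = zlo; z < zhi; ++z) {
            const int iz = z * stride - pad + kz;
            for (int y = ylo; y < yhi; ++y) {
              const int iy = y * stride - pad + ky;
              double *d = gxc + (size_t)nx * (iy + (size_t)ny * iz)
                          - pad + kx;
              const double *s = src + (size_t)ox * (y + (size_t)oy * z);
              if (stride == 1) {
                for (int xo = xlo; xo < xhi; ++xo) d[xo] += s[xo];
              } else {
                for (int xo = xlo; xo < xhi; ++xo)
                  d[(size_t)xo * stride] += s[xo];
              }
            }
          }
        }
  }
  gX.attr("dim") = xdim;
  NumericVector gWr(gW.begin(), gW.end());
  gWr.attr("dim") = IntegerVector::create(k, k, k, cin, cout);
  return List::create(_["gx"] = gX, _["gw"] = gWr,
                      _["gb"] = NumericVector(gB.begin(), gB.end()));
}

// ----------------------------------------------------------------- pooling

// 2x2x2 max pooling, stride 2; odd trailing voxels are dropped (output
// dimension floor(n/2), minimum 1).
// [[Rcpp::export(name = ".cpp_maxpool3d_forward")]]
List cpp_maxpool3d_forward(NumericVector x, IntegerVector xdim) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], c = xdim[3];
  const int ox = std::max(nx / 2, 1), oy = std::max(ny / 2, 1),
            oz = std::max(nz / 2, 1);
  NumericVector out((size_t)ox * oy * oz * c);
  IntegerVector arg((size_t)ox * oy * oz * c);
  const double *xp = x.begin();
  for (int ci = 0; ci < c; ++ci) {
    const size_t xoff = (size_t)ci * nx * ny * nz;
    const size_t ooff = (size_t)ci * ox * oy * oz;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int xo = 0; xo < ox; ++xo) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bidx = 0;
          for (int dz = 0; dz < 2; ++dz) {
            int iz = 2 * z + dz;
            if (iz >= nz) continue;
            for (int dy = 0; dy < 2; ++dy) {
              int iy = 2 * y + dy;
              if (iy >= ny) continue;
              for (int dx = 0; dx < 2; ++dx) {
                int ix = 2 * xo + dx;
                if (ix >= nx) continue;
                size_t idx = xoff + ix + (size_t)nx * (iy + (size_t)ny * iz);
                if (xp[idx] > best) { best = xp[idx]; bidx = idx; }
              }
            }
          }
          size_t o = ooff + xo + (size_t)ox * (y + (size_t)oy * z);
          out[o] = best;
          arg[o] = (int)bidx; // fits: toy/production grids < 2^31 elements
        }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz, c);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".cpp_maxpool3d_backward")]]
NumericVector cpp_maxpool3d_backward(NumericVector gout, IntegerVector argmax,
                                     IntegerVector xdim) {
  NumericVector gx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  for (R_xlen_t i = 0; i < gout.size(); ++i) gx[argmax[i]] += gout[i];
  gx.attr("dim") = xdim;
  return gx;
}

// -------------------------------------------------------------- upsampling

// Trilinear upsampling to an arbitrary target size (half-pixel alignment:
// input coord = (out + 0.5) * n_in / n_out - 0.5, clamped at borders).
static void upsample_weights(int n_in, int n_out, std::vector<int> &i0,
                             std::vector<double> &f) {
  i0.resize(n_out); f.resize(n_out);
  const double s = (double)n_in / n_out;
  for (int o = 0; o < n_out; ++o) {
    double c = (o + 0.5) * s - 0.5;
    if (c < 0) c = 0;
    if (c > n_in - 1) c = n_in - 1;
    int lo = (int)std::floor(c);
    if (lo > n_in - 2) lo = std::max(n_in - 2, 0);
    i0[o] = lo;
    f[o] = (n_in == 1) ? 0.0 : c - lo;
  }
}

// [[Rcpp::export(name = ".cpp_upsample3d_forward")]]
NumericVector cpp_upsample3d_forward(NumericVector x, IntegerVector xdim,
                                     IntegerVector odims) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], c = xdim[3];
  const int ox = odims[0], oy = odims[1], oz = odims[2];
  std::vector<int> ix0, iy0, iz0;
  std::vector<double> fx, fy, fz;
  upsample_weights(nx, ox, ix0, fx);
  upsample_weights(ny, oy, iy0, fy);
  upsample_weights(nz, oz, iz0, fz);
  NumericVector out((size_t)ox * oy * oz * c);
  const double *xp = x.begin();
  double *op = out.begin();
  for (int ci = 0; ci < c; ++ci) {
    const double *xc = xp + (size_t)ci * nx * ny * nz;
    double *oc = op + (size_t)ci * ox * oy * oz;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int xo = 0; xo < ox; ++xo) {
          double acc = 0.0;
          for (int dz = 0; dz < 2; ++dz) {
            double wz = dz ? fz[z] : 1 - fz[z];
            if (wz == 0) continue;
            int iz = std::min(iz0[z] + dz, nz - 1);
            for (int dy = 0; dy < 2; ++dy) {
              double wy = dy ? fy[y] : 1 - fy[y];
              if (wy == 0) continue;
              int iy = std::min(iy0[y] + dy, ny - 1);
              for (int dx = 0; dx < 2; ++dx) {
                double wx = dx ? fx[xo] : 1 - fx[xo];
                if (wx == 0) continue;
                int ix = std::min(ix0[xo] + dx, nx - 1);
                acc += wx * wy * wz *
                       xc[ix + (size_t)nx * (iy + (size_t)ny * iz)];
              }
            }
          }
          oc[xo + (size_t)ox * (y + (size_t)oy * z)] = acc;
        }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz, c);
  return out;
}

// [[Rcpp::export(name = ".cpp_upsample3d_backward")]]
NumericVector cpp_upsample3d_backward(NumericVector gout, IntegerVector odim,
                                      IntegerVector xdim) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], c = xdim[3];
  const int ox = odim[0], oy = odim[1], oz = odim[2];
  std::vector<int> ix0, iy0, iz0;
  std::vector<double> fx, fy, fz;
  upsample_weights(nx, ox, ix0, fx);
  upsample_weights(ny, oy, iy0, fy);
  upsample_weights(nz, oz, iz0, fz);
  NumericVector gx((size_t)nx * ny * nz * c);
  const double *gp = gout.begin();
  double *gxp = gx.begin();
  for (int ci = 0; ci < c; ++ci) {
    const double *gc = gp + (size_t)ci * ox * oy * oz;
    double *xc = gxp + (size_t)ci * nx * ny * nz;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int xo = 0; xo < ox; ++xo) {
          double g = gc[xo + (size_t)ox * (y + (size_t)oy * z)];
          if (g == 0) continue;
          for (int dz = 0; dz < 2; ++dz) {
            double wz = dz ? fz[z] : 1 - fz[z];
            if (wz == 0) continue;
            int iz = std::min(iz0[z] + dz, nz - 1);
            for (int dy = 0; dy < 2; ++dy) {
              double wy = dy ? fy[y] : 1 - fy[y];
              if (wy == 0) continue;
              int iy = std::min(iy0[y] + dy, ny - 1);
              for (int dx = 0; dx < 2; ++dx) {
                double wx = dx ? fx[xo] : 1 - fx[xo];
                if (wx == 0) continue;
                int ix = std::min(ix0[xo] + dx, nx - 1);
                xc[ix + (size_t)nx * (iy + (size_t)ny * iz)] +=
                    g * wx * wy * wz;
              }
            }
          }
        }
  }
  gx.attr("dim") = xdim;
  return gx;
}

// ------------------------------------------------------------------ relu

// [[Rcpp::export(name = ".cpp_relu_forward")]]
NumericVector cpp_relu_forward(NumericVector x) {
  NumericVector out(clone(x));
  double *p = out.begin();
  for (R_xlen_t i = 0; i < out.size(); ++i)
    if (p[i] < 0) p[i] = 0;
  return out;
}

// [[Rcpp::export(name = ".cpp_relu_backward")]]
NumericVector cpp_relu_backward(NumericVector out, NumericVector gout) {
  NumericVector g(clone(gout));
  const double *o = out.begin();
  double *p = g.begin();
  for (R_xlen_t i = 0; i < g.size(); ++i)
    if (o[i] <= 0) p[i] = 0;
  return g;
}

// ------------------------------------------------------------- group norm

// [[Rcpp::export(name = ".cpp_groupnorm_forward")]]
List cpp_groupnorm_forward(NumericVector x, IntegerVector xdim,
                           NumericVector gamma, NumericVector beta,
                           int groups, double eps) {
  const size_t nvox = (size_t)xdim[0] * xdim[1] * xdim[2];
  const int c = xdim[3];
  const int gs = c / groups; // channels per group
  NumericVector out(x.size()), xhat(x.size());
  NumericVector mean(groups), invstd(groups);
  const double *xp = x.begin();
  for (int g = 0; g < groups; ++g) {
    const size_t off = (size_t)g * gs * nvox, n = (size_t)gs * nvox;
    double m = 0;
    for (size_t i = 0; i < n; ++i) m += xp[off + i];
    m /= n;
    double v = 0;
    for (size_t i = 0; i < n; ++i) {
      double d = xp[off + i] - m;
      v += d * d;
    }
    v /= n;
    double is = 1.0 / std::sqrt(v + eps);
    mean[g] = m; invstd[g] = is;
    for (int cc = 0; cc < gs; ++cc) {
      const double ga = gamma[g * gs + cc], be = beta[g * gs + cc];
      const size_t coff = off + (size_t)cc * nvox;
      for (size_t i = 0; i < nvox; ++i) {
        double h = (xp[coff + i] - m) * is;
        xhat[coff + i] = h;
        out[coff + i] = ga * h + be;
      }
    }
  }
  out.attr("dim") = xdim;
  return List::create(_["out"] = out, _["xhat"] = xhat,
                      _["invstd"] = invstd);
}

// [[Rcpp::export(name = ".cpp_groupnorm_backward")]]
List cpp_groupnorm_backward(NumericVector gout, NumericVector xhat,
                            NumericVector invstd, NumericVector gamma,
                            IntegerVector xdim, int groups) {
  const size_t nvox = (size_t)xdim[0] * xdim[1] * xdim[2];
  const int c = xdim[3];
  const int gs = c / groups;
  NumericVector gx(gout.size()), ggamma(c), gbeta(c);
  const double *gp = gout.begin(), *hp = xhat.begin();
  for (int g = 0; g < groups; ++g) {
    const size_t off = (size_t)g * gs * nvox, n = (size_t)gs * nvox;
    // per-channel parameter grads + per-group reductions of dxhat
    double sum_dh = 0, sum_dh_h = 0;
    for (int cc = 0; cc < gs; ++cc) {
      const size_t coff = off + (size_t)cc * nvox;
      const double ga = gamma[g * gs + cc];
      double sg = 0, sb = 0;
      for (size_t i = 0; i < nvox; ++i) {
        const double go = gp[coff + i], h = hp[coff + i];
        sg += go * h;
        sb += go;
        const double dh = go * ga;
        sum_dh += dh;
        sum_dh_h += dh * h;
      }
      ggamma[g * gs + cc] = sg;
      gbeta[g * gs + cc] = sb;
    }
    const double is = invstd[g];
    for (int cc = 0; cc < gs; ++cc) {
      const size_t coff = off + (size_t)cc * nvox;
      const double ga = gamma[g * gs + cc];
      for (size_t i = 0; i < nvox; ++i) {
        const double dh = gp[coff + i] * ga;
        gx[coff + i] =
            is * (dh - sum_dh / n - hp[coff + i] * sum_dh_h / n);
      }
    }
  }
  gx.attr("dim") = xdim;
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}
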