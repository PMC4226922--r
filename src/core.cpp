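#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Image interpolation: Keys cubic convolution (a = -0.5), constant extension
// at the border.  Interpolatory (no prefilter) and analytically differentiable,
// which keeps transform-coefficient gradients exact.
// ---------------------------------------------------------------------------

static inline double keys_w(double s) {
  s = std::fabs(s);
  if (s < 1.0) return ((1.5 * s - 2.5) * s) * s + 1.0;
  if (s < 2.0) return (((-0.5 * s) + 2.5) * s - 4.0) * s + 2.0;
  return 0.0;
}

// derivative of keys_w with respect to signed s
static inline double keys_dw(double s) {
  double sign = (s < 0) ? -1.0 : 1.0;
  double a = std::fabs(s);
  if (a < 1.0) return sign * ((4.5 * a - 5.0) * a);
  if (a < 2.0) return sign * ((-1.5 * a + 5.0) * a - 4.0);
  return 0.0;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// sample image (and optionally its spatial derivative) at continuous (y, x),
// 0-based pixel coordinates
static inline void sample_cubic(const double* img, int nr, int nc,
                                double y, double x,
                                double* val, double* dy, double* dx) {
  int iy = (int)std::floor(y);
  int ix = (int)std::floor(x);
  double wy[4], wx[4], dwy[4], dwx[4];
  int ry[4], rx[4];
  for (int k = 0; k < 4; ++k) {
    double sy = y - (double)(iy - 1 + k);
    double sx = x - (double)(ix - 1 + k);
    wy[k] = keys_w(sy); wx[k] = keys_w(sx);
    // d/dy of w(y - node) = keys_dw(s)
    dwy[k] = keys_dw(sy); dwx[k] = keys_dw(sx);
    ry[k] = clampi(iy - 1 + k, 0, nr - 1);
    rx[k] = clampi(ix - 1 + k, 0, nc - 1);
  }
  double v = 0.0, gy = 0.0, gx = 0.0;
  for (int a = 0; a < 4; ++a) {
    for (int b = 0; b < 4; ++b) {
      double p = img[ry[a] + nr * rx[b]];
      v  += wy[a] * wx[b] * p;
      gy += dwy[a] * wx[b] * p;
      gx += wy[a] * dwx[b] * p;
    }
  }
  *val = v;
  if (dy) *dy = gy;
  if (dx) *dx = gx;
}

// [[Rcpp::export]]
NumericMatrix cpp_warp_image(NumericMatrix img, NumericMatrix uy, NumericMatrix ux) {
  int nr = img.nrow(), nc = img.ncol();
  if (uy.nrow() != nr || uy.ncol() != nc || ux.nrow() != nr || ux.ncol() != nc)
    stop("displacement fields must match image shape");
  NumericMatrix out(nr, nc);
  const double* p = img.begin();
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double v;
      sample_cubic(p, nr, nc, r + uy(r, c), c + ux(r, c), &v, 0, 0);
      out(r, c) = v;
    }
  return out;
}

// nearest-neighbour pull-back for masks; samples falling outside the domain
// map to 0
// [[Rcpp::export]]
IntegerMatrix cpp_warp_mask(IntegerMatrix mask, NumericMatrix uy, NumericMatrix ux) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double y = r + uy(r, c), x = c + ux(r, c);
      int ry = (int)std::lround(y), rx = (int)std::lround(x);
      if (ry < 0 || ry >= nr || rx < 0 || rx >= nc) { out(r, c) = 0; continue; }
      out(r, c) = mask(ry, rx);
    }
  return out;
}

// bilinear interpolation of a field at arbitrary points (clamped)
// [[Rcpp::export]]
NumericVector cpp_interp2_bilinear(NumericMatrix f, NumericVector ys, NumericVector xs) {
  int nr = f.nrow(), nc = f.ncol(), n = ys.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double y = ys[i], x = xs[i];
    if (y < 0) y = 0; if (y > nr - 1) y = nr - 1;
    if (x < 0) x = 0; if (x > nc - 1) x = nc - 1;
    int r0 = (int)std::floor(y), c0 = (int)std::floor(x);
    int r1 = std::min(r0 + 1, nr - 1), c1 = std::min(c0 + 1, nc - 1);
    double fy = y - r0, fx = x - c0;
    out[i] = (1 - fy) * (1 - fx) * f(r0, c0) + (1 - fy) * fx * f(r0, c1) +
             fy * (1 - fx) * f(r1, c0) + fy * fx * f(r1, c1);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Cubic B-spline free-form deformation.  Uniform knot grid with spacing h
// (working pixels); coefficient grid of size floor((n-1)/h) + 4 per axis so
// the 4-knot support always exists.  Zero coefficients give the identity.
// ---------------------------------------------------------------------------

static inline void bsp_w(double t, double* w) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
  w[1] = (4.0 - 6.0 * t2 + 3.0 * t3) / 6.0;
  w[2] = (1.0 + 3.0 * t + 3.0 * t2 - 3.0 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

// [[Rcpp::export]]
int cpp_bspline_grid_dim(int n, double h) {
  return (int)std::floor((double)(n - 1) / h) + 4;
}

// evaluate displacement at arbitrary working coordinates
// [[Rcpp::export]]
List cpp_eval_bspline_disp(NumericMatrix cy, NumericMatrix cx, double h,
                           NumericVector ys, NumericVector xs) {
  int n = ys.size();
  int ngy = cy.nrow(), ngx = cy.ncol();
  NumericVector uy(n), ux(n);
  double wy[4], wx[4];
  for (int i = 0; i < n; ++i) {
    double gy = ys[i] / h, gx = xs[i] / h;
    int iy = (int)std::floor(gy), ix = (int)std::floor(gx);
    bsp_w(gy - iy, wy); bsp_w(gx - ix, wx);
    double sy = 0.0, sx = 0.0;
    for (int a = 0; a < 4; ++a) {
      int r = clampi(iy + a, 0, ngy - 1);
      for (int b = 0; b < 4; ++b) {
        int c = clampi(ix + b, 0, ngx - 1);
        double w = wy[a] * wx[b];
        sy += w * cy(r, c);
        sx += w * cx(r, c);
      }
    }
    uy[i] = sy; ux[i] = sx;
  }
  return List::create(_["uy"] = uy, _["ux"] = ux);
}

// ---------------------------------------------------------------------------
// Curvature (bending energy) of the displacement: discrete second differences
// over interior pixels, mean over all pixels and both displacement
// components.  Zero for any affine displacement field.
// ---------------------------------------------------------------------------

static double curvature_cost_adj(const std::vector<double>& u, int nr, int nc,
                                 double step, std::vector<double>* adj) {
  double cost = 0.0;
  double s2 = step * step, s4 = s2 * s2;
  // d_yy and d_xx
  for (int c = 0; c < nc; ++c)
    for (int r = 1; r < nr - 1; ++r) {
      double d = (u[r - 1 + nr * c] - 2.0 * u[r + nr * c] + u[r + 1 + nr * c]) / s2;
      cost += d * d;
      if (adj) {
        double g = 2.0 * d / s2;
        (*adj)[r - 1 + nr * c] += g;
        (*adj)[r + nr * c]     -= 2.0 * g;
        (*adj)[r + 1 + nr * c] += g;
      }
    }
  for (int c = 1; c < nc - 1; ++c)
    for (int r = 0; r < nr; ++r) {
      double d = (u[r + nr * (c - 1)] - 2.0 * u[r + nr * c] + u[r + nr * (c + 1)]) / s2;
      cost += d * d;
      if (adj) {
        double g = 2.0 * d / s2;
        (*adj)[r + nr * (c - 1)] += g;
        (*adj)[r + nr * c]       -= 2.0 * g;
        (*adj)[r + nr * (c + 1)] += g;
      }
    }
  // 2 * d_xy^2 (central cross differences)
  for (int c = 1; c < nc - 1; ++c)
    for (int r = 1; r < nr - 1; ++r) {
      double d = (u[r + 1 + nr * (c + 1)] - u[r + 1 + nr * (c - 1)]
                  - u[r - 1 + nr * (c + 1)] + u[r - 1 + nr * (c - 1)]) / (4.0 * s2);
      cost += 2.0 * d * d;
      if (adj) {
        double g = 4.0 * d / (4.0 * s2);
        (*adj)[r + 1 + nr * (c + 1)] += g;
        (*adj)[r + 1 + nr * (c - 1)] -= g;
        (*adj)[r - 1 + nr * (c + 1)] -= g;
        (*adj)[r - 1 + nr * (c - 1)] += g;
      }
    }
  (void)s4;
  return cost;
}

// ---------------------------------------------------------------------------
// Registration objective: similarity(measure) + kappa * curvature, with
// analytic gradient with respect to the B-spline coefficients.
//
// The level image has shape (nr, nc); level pixel (r, c) corresponds to
// working coordinate (r * fac + off, c * fac + off) with off = (fac - 1) / 2
// (block-mean downsampling aligns block centres).  Displacements are stored
// in working pixels; sampling the level image divides by fac.
// measure: 0 = SSD, 1 = NGF.
// ---------------------------------------------------------------------------

// NGF machinery: gradients of the level image by central differences with
// clamped (replicated) borders.
static void grad_central(const std::vector<double>& im, int nr, int nc,
                         std::vector<double>& gy, std::vector<double>& gx) {
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int rm = clampi(r - 1, 0, nr - 1), rp = clampi(r + 1, 0, nr - 1);
      int cm = clampi(c - 1, 0, nc - 1), cp = clampi(c + 1, 0, nc - 1);
      gy[r + nr * c] = 0.5 * (im[rp + nr * c] - im[rm + nr * c]);
      gx[r + nr * c] = 0.5 * (im[r + nr * cp] - im[r + nr * cm]);
    }
}

// adjoint of grad_central: given dC/dgy, dC/dgx accumulate dC/dim
static void grad_central_adj(const std::vector<double>& ay,
                             const std::vector<double>& ax,
                             int nr, int nc, std::vector<double>& aim) {
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int rm = clampi(r - 1, 0, nr - 1), rp = clampi(r + 1, 0, nr - 1);
      int cm = clampi(c - 1, 0, nc - 1), cp = clampi(c + 1, 0, nc - 1);
      aim[rp + nr * c] += 0.5 * ay[r + nr * c];
      aim[rm + nr * c] -= 0.5 * ay[r + nr * c];
      aim[r + nr * cp] += 0.5 * ax[r + nr * c];
      aim[r + nr * cm] -= 0.5 * ax[r + nr * c];
    }
}

// [[Rcpp::export]]
List cpp_reg_cost_grad(NumericMatrix cy, NumericMatrix cx,
                       NumericMatrix mov, NumericMatrix ref,
                       double h, double fac, double kappa,
                       int measure, double eta, bool want_grad) {
  int nr = mov.nrow(), nc = mov.ncol();
  if (ref.nrow() != nr || ref.ncol() != nc) stop("image shape mismatch");
  int ngy = cy.nrow(), ngx = cy.ncol();
  int N = nr * nc;
  double off = (fac - 1.0) / 2.0;

  std::vector<double> uy(N), ux(N);        // working px
  std::vector<double> mw(N);               // warped moving (level grid)
  std::vector<double> mdy(N), mdx(N);      // d(warped)/d(level coord)
  std::vector<int>    kiy(N), kix(N);      // knot anchor per pixel
  std::vector<double> wgy(4 * N), wgx(4 * N);

  const double* movp = mov.begin();

  double wy[4], wx[4];
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int idx = r + nr * c;
      double Y = r * fac + off, X = c * fac + off;   // working coords
      double gy = Y / h, gx = X / h;
      int iy = (int)std::floor(gy), ix = (int)std::floor(gx);
      bsp_w(gy - iy, wy); bsp_w(gx - ix, wx);
      kiy[idx] = iy; kix[idx] = ix;
      double sy = 0.0, sx = 0.0;
      for (int a = 0; a < 4; ++a) {
        wgy[4 * idx + a] = wy[a];
        wgx[4 * idx + a] = wx[a];
      }
      for (int a = 0; a < 4; ++a) {
        int rr = clampi(iy + a, 0, ngy - 1);
        for (int b = 0; b < 4; ++b) {
          int cc = clampi(ix + b, 0, ngx - 1);
          double w = wy[a] * wx[b];
          sy += w * cy(rr, cc);
          sx += w * cx(rr, cc);
        }
      }
      uy[idx] = sy; ux[idx] = sx;
      double v, dy, dx;
      sample_cubic(movp, nr, nc, r + sy / fac, c + sx / fac, &v, &dy, &dx);
      mw[idx] = v; mdy[idx] = dy; mdx[idx] = dx;
    }

  double cost = 0.0;
  std::vector<double> dC_dmw(N, 0.0);      // dCost / d(warped image value)

  if (measure == 0) {                       // SSD: 0.5 * mean((mw - ref)^2)
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        int idx = r + nr * c;
        double d = mw[idx] - ref(r, c);
        cost += 0.5 * d * d;
        dC_dmw[idx] = d / N;
      }
    cost /= N;
  } else {                                  // NGF: mean(1 - <n(mw), n(ref)>^2)
    std::vector<double> rim(N);
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) rim[r + nr * c] = ref(r, c);
    std::vector<double> rgy(N), rgx(N), mgy(N), mgx(N);
    grad_central(rim, nr, nc, rgy, rgx);
    grad_central(mw, nr, nc, mgy, mgx);
    double e2 = eta * eta;
    std::vector<double> agy(N, 0.0), agx(N, 0.0);
    for (int i = 0; i < N; ++i) {
      double a = mgy[i] * rgy[i] + mgx[i] * rgx[i];
      double b = mgy[i] * mgy[i] + mgx[i] * mgx[i] + e2;
      double d = rgy[i] * rgy[i] + rgx[i] * rgx[i] + e2;
      cost += 1.0 - a * a / (b * d);
      if (want_grad) {
        // d/dmg of -(a^2)/(b d)
        double c1 = -2.0 * a / (b * d);
        double c2 = 2.0 * a * a / (b * b * d);
        agy[i] = (c1 * rgy[i] + c2 * mgy[i]) / N;
        agx[i] = (c1 * rgx[i] + c2 * mgx[i]) / N;
      }
    }
    cost /= N;
    if (want_grad) grad_central_adj(agy, agx, nr, nc, dC_dmw);
  }

  // curvature penalty on the level grid (working-pixel units)
  std::vector<double> ady, adx;
  if (kappa > 0.0) {
    if (want_grad) { ady.assign(N, 0.0); adx.assign(N, 0.0); }
    double p = curvature_cost_adj(uy, nr, nc, fac, want_grad ? &ady : 0)
             + curvature_cost_adj(ux, nr, nc, fac, want_grad ? &adx : 0);
    cost += kappa * p / N;
  }

  if (!want_grad)
    return List::create(_["cost"] = cost);

  NumericMatrix gcy(ngy, ngx), gcx(ngy, ngx);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int idx = r + nr * c;
      // dC/d(uy), dC/d(ux) in working px at this pixel
      double duy = dC_dmw[idx] * mdy[idx] / fac;
      double dux = dC_dmw[idx] * mdx[idx] / fac;
      if (kappa > 0.0) {
        duy += kappa * ady[idx] / N;
        dux += kappa * adx[idx] / N;
      }
      if (duy == 0.0 && dux == 0.0) continue;
      for (int a = 0; a < 4; ++a) {
        int rr = clampi(kiy[idx] + a, 0, ngy - 1);
        double wa = wgy[4 * idx + a];
        for (int b = 0; b < 4; ++b) {
          int cc = clampi(kix[idx] + b, 0, ngx - 1);
          double w = wa * wgx[4 * idx + b];
          gcy(rr, cc) += w * duy;
          gcx(rr, cc) += w * dux;
        }
      }
    }
  return List::create(_["cost"] = cost, _["gcy"] = gcy, _["gcx"] = gcx);
}

// standalone curvature penalty (cost + coefficient gradient) for a transform
// evaluated over its full working domain
// [[Rcpp::export]]
List cpp_curv_cost_grad(NumericMatrix cy, NumericMatrix cx, double h,
                        int nr, int nc, bool want_grad) {
  int ngy = cy.nrow(), ngx = cy.ncol();
  int N = nr * nc;
  std::vector<double> uy(N), ux(N);
  std::vector<int> kiy(N), kix(N);
  std::vector<double> wgy(4 * N), wgx(4 * N);
  double wy[4], wx[4];
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int idx = r + nr * c;
      double gy = r / h, gx = c / h;
      int iy = (int)std::floor(gy), ix = (int)std::floor(gx);
      bsp_w(gy - iy, wy); bsp_w(gx - ix, wx);
      kiy[idx] = iy; kix[idx] = ix;
      double sy = 0.0, sx = 0.0;
      for (int a = 0; a < 4; ++a) { wgy[4 * idx + a] = wy[a]; wgx[4 * idx + a] = wx[a]; }
      for (int a = 0; a < 4; ++a) {
        int rr = clampi(iy + a, 0, ngy - 1);
        for (int b = 0; b < 4; ++b) {
          int cc = clampi(ix + b, 0, ngx - 1);
          double w = wy[a] * wx[b];
          sy += w * cy(rr, cc); sx += w * cx(rr, cc);
        }
      }
      uy[idx] = sy; ux[idx] = sx;
    }
  std::vector<double> ady, adx;
  if (want_grad) { ady.assign(N, 0.0); adx.assign(N, 0.0); }
  double cost = (curvature_cost_adj(uy, nr, nc, 1.0, want_grad ? &ady : 0)
               + curvature_cost_adj(ux, nr, nc, 1.0, want_grad ? &adx : 0)) / N;
  if (!want_grad) return List::create(_["cost"] = cost);
  NumericMatrix gcy(ngy, ngx), gcx(ngy, ngx);
  for (int idx = 0; idx < N; ++idx) {
    double duy = ady[idx] / N, dux = adx[idx] / N;
    if (duy == 0.0 && dux == 0.0) continue;
    for (int a = 0; a < 4; ++a) {
      int rr = clampi(kiy[idx] + a, 0, ngy - 1);
      double wa = wgy[4 * idx + a];
      for (int b = 0; b < 4; ++b) {
        int cc = clampi(kix[idx] + b, 0, ngx - 1);
        double w = wa * wgx[4 * idx + b];
        gcy(rr, cc) += w * duy;
        gcx(rr, cc) += w * dux;
      }
    }
  }
  return List::create(_["cost"] = cost, _["gcy"] = gcy, _["gcx"] = gcx);
}

// ---------------------------------------------------------------------------
// block-mean 2x downsampling (odd trailing row/col averaged over what exists)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_downsample2(NumericMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  int mr = (nr + 1) / 2, mc = (nc + 1) / 2;
  NumericMatrix out(mr, mc);
  for (int c = 0; c < mc; ++c)
    for (int r = 0; r < mr; ++r) {
      double s = 0.0; int n = 0;
      for (int dr = 0; dr < 2; ++dr)
        for (int dc = 0; dc < 2; ++dc) {
          int rr = 2 * r + dr, cc = 2 * c + dc;
          if (rr < nr && cc < nc) { s += img(rr, cc); ++n; }
        }
      out(r, c) = s / n;
    }
  return out;
}

// ---------------------------------------------------------------------------
// polygon rasterization: even-odd (crossing-number) test of each pixel
// centre, 0-based (x = column, y = row) vertex coordinates
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_rasterize_polygon(NumericVector xs, NumericVector ys,
                                    int nrow, int ncol) {
  int nv = xs.size();
  IntegerMatrix out(nrow, ncol);
  for (int c = 0; c < ncol; ++c)
    for (int r = 0; r < nrow; ++r) {
      double px = (double)c, py = (double)r;
      bool inside = false;
      for (int i = 0, j = nv - 1; i < nv; j = i++) {
        if (((ys[i] > py) != (ys[j] > py)) &&
            (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i]))
          inside = !inside;
      }
      out(r, c) = inside ? 1 : 0;
    }
  return out;
}

// ---------------------------------------------------------------------------
// 4-connected component labelling of a binary mask
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<int> q;
  for (int c0 = 0; c0 < nc; ++c0)
    for (int r0 = 0; r0 < nr; ++r0) {
      if (mask(r0, c0) == 0 || lab(r0, c0) != 0) continue;
      ++next;
      lab(r0, c0) = next;
      q.push(r0 + nr * c0);
      while (!q.empty()) {
        int idx = q.front(); q.pop();
        int r = idx % nr, c = idx / nr;
        const int dr[4] = {1, -1, 0, 0}, dc[4] = {0, 0, 1, -1};
        for (int k = 0; k < 4; ++k) {
          int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(rr + nr * cc);
          }
        }
      }
    }
  return lab;
}
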