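// Numerical kernels: 2D conv layers (im2col/GEMM), bilinear warping with
// analytic gradients, 3D resampling/blurring, cubic B-spline displacement
// fields, gamma-index search, connected components, beam ray-marching.
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <queue>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// im2col / col2im, pixel-major layout: cols is (oh*ow) x (C*k*k) so the
// inner loop writes contiguously; row j = oc*oh + orr, col q = c*k*k+kc*k+kr.
// ---------------------------------------------------------------------------

static arma::mat im2colT(const arma::cube& x, int k, int s, int p,
                         int& oh, int& ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  oh = (H + 2 * p - k) / s + 1;
  ow = (W + 2 * p - k) / s + 1;
  arma::mat cols(oh * ow, C * k * k, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kc = 0; kc < k; ++kc)
      for (int kr = 0; kr < k; ++kr) {
        const int q = c * k * k + kc * k + kr;
        double* dst = cols.colptr(q);
        for (int oc = 0; oc < ow; ++oc) {
          const int ic = oc * s - p + kc;
          if (ic < 0 || ic >= W) continue;
          const double* src = x.slice_colptr(c, ic);
          for (int orr = 0; orr < oh; ++orr) {
            const int ir = orr * s - p + kr;
            if (ir < 0 || ir >= H) continue;
            dst[oc * oh + orr] = src[ir];
          }
        }
      }
  return cols;
}

static arma::cube col2imT(const arma::mat& cols, int H, int W, int C,
                          int k, int s, int p) {
  const int oh = (H + 2 * p - k) / s + 1;
  const int ow = (W + 2 * p - k) / s + 1;
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kc = 0; kc < k; ++kc)
      for (int kr = 0; kr < k; ++kr) {
        const int q = c * k * k + kc * k + kr;
        const double* src = cols.colptr(q);
        for (int oc = 0; oc < ow; ++oc) {
          const int ic = oc * s - p + kc;
          if (ic < 0 || ic >= W) continue;
          double* dst = x.slice_colptr(c, ic);
          for (int orr = 0; orr < oh; ++orr) {
            const int ir = orr * s - p + kr;
            if (ir < 0 || ir >= H) continue;
            dst[ir] += src[oc * oh + orr];
          }
        }
      }
  return x;
}

// view the cube's memory as an (H*W) x C matrix (no copy)
static arma::mat cube_as_mat(const arma::cube& x) {
  return arma::mat(const_cast<double*>(x.memptr()), x.n_rows * x.n_cols,
                   x.n_slices, false, true);
}

// ---------------------------------------------------------------------------
// Strided convolution: W is (outC x inC*k*k), b length outC.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::cube conv2d_fwd_cpp(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, int k, int s, int p) {
  int oh, ow;
  arma::mat cols = im2colT(x, k, s, p, oh, ow);
  arma::mat Y = cols * W.t();       // (oh*ow) x outC
  Y.each_row() += b.t();
  const int outC = W.n_rows;
  arma::cube out(oh, ow, outC);
  std::copy(Y.begin(), Y.end(), out.memptr());
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(const arma::cube& x, const arma::mat& W,
                    const arma::cube& dout, int k, int s, int p) {
  int oh, ow;
  arma::mat cols = im2colT(x, k, s, p, oh, ow);
  arma::mat dY = cube_as_mat(dout); // (oh*ow) x outC
  arma::mat dW = dY.t() * cols;     // outC x (C*k*k)
  arma::vec db = arma::sum(dY, 0).t();
  arma::mat dcols = dY * W;         // (oh*ow) x (C*k*k)
  arma::cube dx = col2imT(dcols, x.n_rows, x.n_cols, x.n_slices, k, s, p);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// ---------------------------------------------------------------------------
// Transposed convolution (stride-2 upsampling). W is (inC x outC*k*k).
// Forward is the adjoint of a conv that maps (OH,OW) -> (H,W).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::cube convt2d_fwd_cpp(const arma::cube& x, const arma::mat& W,
                           const arma::vec& b, int k, int s, int p) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int OH = (H - 1) * s - 2 * p + k;
  const int OW = (Wd - 1) * s - 2 * p + k;
  const int outC = W.n_cols / (k * k);
  arma::mat X = cube_as_mat(x);     // (H*Wd) x inC
  arma::mat cols = X * W;           // (H*Wd) x (outC*k*k)
  arma::cube out = col2imT(cols, OH, OW, outC, k, s, p);
  for (int c = 0; c < outC; ++c)
    out.slice(c) += b(c);
  return out;
}

// [[Rcpp::export]]
List convt2d_bwd_cpp(const arma::cube& x, const arma::mat& W,
                     const arma::cube& dout, int k, int s, int p) {
  const int H = x.n_rows, Wd = x.n_cols, inC = x.n_slices;
  int oh, ow;
  arma::mat dcols = im2colT(dout, k, s, p, oh, ow);  // (H*Wd) x (outC*k*k)
  arma::mat X = cube_as_mat(x);
  arma::mat dX = dcols * W.t();     // (H*Wd) x inC
  arma::cube dx(H, Wd, inC);
  std::copy(dX.begin(), dX.end(), dx.memptr());
  arma::mat dW = X.t() * dcols;     // inC x (outC*k*k)
  const int outC = dout.n_slices;
  arma::vec db(outC);
  for (int c = 0; c < outC; ++c)
    db(c) = arma::accu(dout.slice(c));
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// ---------------------------------------------------------------------------
// Bilinear warp of a single-channel slice by a per-pixel displacement field
// (voxel units): out(r,c) = img(r + f0, c + f1), border-clamped.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::mat warp2d_fwd_cpp(const arma::mat& img, const arma::cube& field) {
  const int H = img.n_rows, W = img.n_cols;
  arma::mat out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double rr = r + field.at(r, c, 0);
      double cc = c + field.at(r, c, 1);
      if (rr < 0) rr = 0; if (rr > H - 1) rr = H - 1;
      if (cc < 0) cc = 0; if (cc > W - 1) cc = W - 1;
      const int r0 = (int)std::floor(rr), c0 = (int)std::floor(cc);
      const int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
      const double fr = rr - r0, fc = cc - c0;
      out.at(r, c) =
        (1 - fr) * (1 - fc) * img.at(r0, c0) + (1 - fr) * fc * img.at(r0, c1) +
        fr * (1 - fc) * img.at(r1, c0) + fr * fc * img.at(r1, c1);
    }
  return out;
}

// [[Rcpp::export]]
List warp2d_bwd_cpp(const arma::mat& img, const arma::cube& field,
                    const arma::mat& dout) {
  const int H = img.n_rows, W = img.n_cols;
  arma::mat dimg(H, W, arma::fill::zeros);
  arma::cube dfield(H, W, 2, arma::fill::zeros);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double rr = r + field.at(r, c, 0);
      double cc = c + field.at(r, c, 1);
      bool clr = false, clc = false;
      if (rr < 0) { rr = 0; clr = true; }
      if (rr > H - 1) { rr = H - 1; clr = true; }
      if (cc < 0) { cc = 0; clc = true; }
      if (cc > W - 1) { cc = W - 1; clc = true; }
      const int r0 = (int)std::floor(rr), c0 = (int)std::floor(cc);
      const int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
      const double fr = rr - r0, fc = cc - c0;
      const double g = dout.at(r, c);
      dimg.at(r0, c0) += g * (1 - fr) * (1 - fc);
      dimg.at(r0, c1) += g * (1 - fr) * fc;
      dimg.at(r1, c0) += g * fr * (1 - fc);
      dimg.at(r1, c1) += g * fr * fc;
      if (!clr)
        dfield.at(r, c, 0) = g * ((1 - fc) * (img.at(r1, c0) - img.at(r0, c0)) +
                                  fc * (img.at(r1, c1) - img.at(r0, c1)));
      if (!clc)
        dfield.at(r, c, 1) = g * ((1 - fr) * (img.at(r0, c1) - img.at(r0, c0)) +
                                  fr * (img.at(r1, c1) - img.at(r1, c0)));
    }
  return List::create(_["dimg"] = dimg, _["dfield"] = dfield);
}

// ---------------------------------------------------------------------------
// 3D helpers on plain arrays indexed (i1,i2,i3), first index fastest.
// ---------------------------------------------------------------------------

static inline double tri_sample(const double* v, const int* d,
                                double x1, double x2, double x3) {
  if (x1 < 0) x1 = 0; if (x1 > d[0] - 1) x1 = d[0] - 1;
  if (x2 < 0) x2 = 0; if (x2 > d[1] - 1) x2 = d[1] - 1;
  if (x3 < 0) x3 = 0; if (x3 > d[2] - 1) x3 = d[2] - 1;
  const int a0 = (int)std::floor(x1), b0 = (int)std::floor(x2),
            c0 = (int)std::floor(x3);
  const int a1 = std::min(a0 + 1, d[0] - 1), b1 = std::min(b0 + 1, d[1] - 1),
            c1 = std::min(c0 + 1, d[2] - 1);
  const double fa = x1 - a0, fb = x2 - b0, fc = x3 - c0;
  #define V(i,j,k) v[(i) + d[0] * ((j) + (size_t)d[1] * (k))]
  const double v00 = (1 - fa) * V(a0, b0, c0) + fa * V(a1, b0, c0);
  const double v10 = (1 - fa) * V(a0, b1, c0) + fa * V(a1, b1, c0);
  const double v01 = (1 - fa) * V(a0, b0, c1) + fa * V(a1, b0, c1);
  const double v11 = (1 - fa) * V(a0, b1, c1) + fa * V(a1, b1, c1);
  #undef V
  const double w0 = (1 - fb) * v00 + fb * v10;
  const double w1 = (1 - fb) * v01 + fb * v11;
  return (1 - fc) * w0 + fc * w1;
}

// Backward warp: out(p) = vol(p + f(p)); mode 0 trilinear, 1 nearest.
// [[Rcpp::export]]
NumericVector warp3d_cpp(NumericVector vol, NumericVector field,
                         IntegerVector dims, int mode) {
  const int d[3] = { dims[0], dims[1], dims[2] };
  const size_t n = (size_t)d[0] * d[1] * d[2];
  NumericVector out(n);
  const double* v = vol.begin();
  const double* f = field.begin();
  size_t idx = 0;
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i, ++idx) {
        double x1 = i + f[idx], x2 = j + f[idx + n], x3 = k + f[idx + 2 * n];
        if (mode == 1) {
          int a = (int)std::lround(x1), b = (int)std::lround(x2),
              c = (int)std::lround(x3);
          if (a < 0) a = 0; if (a > d[0] - 1) a = d[0] - 1;
          if (b < 0) b = 0; if (b > d[1] - 1) b = d[1] - 1;
          if (c < 0) c = 0; if (c > d[2] - 1) c = d[2] - 1;
          out[idx] = v[a + d[0] * ((size_t)b + d[1] * c)];
        } else {
          out[idx] = tri_sample(v, d, x1, x2, x3);
        }
      }
  out.attr("dim") = dims;
  return out;
}

// Resample `moving` onto a fixed grid under a rigid map applied to world
// coordinates of the fixed grid: x' = R (x - center) + center + t.
// World coordinate of index i on a grid: origin + spacing * i (per axis).
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector moving, IntegerVector mdim,
                                  NumericVector mspacing, NumericVector morigin,
                                  IntegerVector fdim, NumericVector fspacing,
                                  NumericVector forigin, NumericMatrix R,
                                  NumericVector t, NumericVector center,
                                  double background) {
  const int md[3] = { mdim[0], mdim[1], mdim[2] };
  const size_t n = (size_t)fdim[0] * fdim[1] * fdim[2];
  NumericVector out(n);
  const double* v = moving.begin();
  size_t idx = 0;
  for (int k = 0; k < fdim[2]; ++k)
    for (int j = 0; j < fdim[1]; ++j)
      for (int i = 0; i < fdim[0]; ++i, ++idx) {
        const double w[3] = { forigin[0] + fspacing[0] * i - center[0],
                              forigin[1] + fspacing[1] * j - center[1],
                              forigin[2] + fspacing[2] * k - center[2] };
        double x[3];
        for (int a = 0; a < 3; ++a)
          x[a] = R(a, 0) * w[0] + R(a, 1) * w[1] + R(a, 2) * w[2] +
                 center[a] + t[a];
        const double u1 = (x[0] - morigin[0]) / mspacing[0];
        const double u2 = (x[1] - morigin[1]) / mspacing[1];
        const double u3 = (x[2] - morigin[2]) / mspacing[2];
        if (u1 < -0.5 || u1 > md[0] - 0.5 || u2 < -0.5 || u2 > md[1] - 0.5 ||
            u3 < -0.5 || u3 > md[2] - 0.5)
          out[idx] = background;
        else
          out[idx] = tri_sample(v, md, u1, u2, u3);
      }
  out.attr("dim") = fdim;
  return out;
}

// Separable Gaussian blur, sigma in voxels per axis; edge-renormalized.
// [[Rcpp::export]]
NumericVector gauss_blur3_cpp(NumericVector vol, IntegerVector dims,
                              NumericVector sigma) {
  const int d[3] = { dims[0], dims[1], dims[2] };
  const size_t n = (size_t)d[0] * d[1] * d[2];
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  const size_t str[3] = { 1, (size_t)d[0], (size_t)d[0] * d[1] };
  for (int ax = 0; ax < 3; ++ax) {
    if (sigma[ax] <= 0) continue;
    const int rad = std::max(1, (int)std::ceil(3.0 * sigma[ax]));
    std::vector<double> ker(2 * rad + 1);
    for (int m = -rad; m <= rad; ++m)
      ker[m + rad] = std::exp(-0.5 * m * m / (sigma[ax] * sigma[ax]));
    const int L = d[ax];
    const size_t s = str[ax];
    // iterate over all lines along axis ax
    const int o1 = (ax == 0) ? 1 : 0;
    const int d1 = d[o1];
    const int o2 = (ax == 2) ? 1 : 2;
    const int d2 = d[o2];
    const size_t s1 = str[o1], s2 = str[o2];
    for (int j2 = 0; j2 < d2; ++j2)
      for (int j1 = 0; j1 < d1; ++j1) {
        const size_t base = j1 * s1 + j2 * s2;
        for (int i = 0; i < L; ++i) {
          double acc = 0, wsum = 0;
          const int lo = std::max(0, i - rad), hi = std::min(L - 1, i + rad);
          for (int m = lo; m <= hi; ++m) {
            const double w = ker[m - i + rad];
            acc += w * a[base + m * s];
            wsum += w;
          }
          b[base + i * s] = acc / wsum;
        }
      }
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Cubic B-spline displacement field. Control grid spacing sp (voxels);
// control point m covers knot index m-1. coef dims: (n1,n2,n3,3).
// ---------------------------------------------------------------------------

static void bsp_weights(int dim, double sp, std::vector<int>& base,
                        std::vector<double>& w) {
  base.resize(dim);
  w.resize(4 * dim);
  for (int v = 0; v < dim; ++v) {
    const double tpos = v / sp;
    const int i = (int)std::floor(tpos);
    const double u = tpos - i;
    base[v] = i;
    const double u2 = u * u, u3 = u2 * u;
    w[4 * v + 0] = (1 - 3 * u + 3 * u2 - u3) / 6.0;
    w[4 * v + 1] = (4 - 6 * u2 + 3 * u3) / 6.0;
    w[4 * v + 2] = (1 + 3 * u + 3 * u2 - 3 * u3) / 6.0;
    w[4 * v + 3] = u3 / 6.0;
  }
}

// [[Rcpp::export]]
int bspline_ncoef_cpp(int dim, double sp) {
  return (int)std::floor((dim - 1) / sp) + 4;
}

// [[Rcpp::export]]
NumericVector bspline_eval_cpp(NumericVector coef, IntegerVector ncp,
                               IntegerVector dims, NumericVector sp) {
  const int d[3] = { dims[0], dims[1], dims[2] };
  const int n1 = ncp[0], n2 = ncp[1], n3 = ncp[2];
  const size_t nvox = (size_t)d[0] * d[1] * d[2];
  const size_t ncoef = (size_t)n1 * n2 * n3;
  NumericVector field(nvox * 3);
  std::vector<int> b1, b2, b3;
  std::vector<double> w1, w2, w3;
  bsp_weights(d[0], sp[0], b1, w1);
  bsp_weights(d[1], sp[1], b2, w2);
  bsp_weights(d[2], sp[2], b3, w3);
  const double* cf = coef.begin();
  for (int comp = 0; comp < 3; ++comp) {
    const double* cc = cf + comp * ncoef;
    double* out = field.begin() + comp * nvox;
    size_t idx = 0;
    for (int k = 0; k < d[2]; ++k)
      for (int j = 0; j < d[1]; ++j)
        for (int i = 0; i < d[0]; ++i, ++idx) {
          double acc = 0;
          for (int mk = 0; mk < 4; ++mk) {
            const double wk = w3[4 * k + mk];
            const size_t ok = (size_t)(b3[k] + mk) * n1 * n2;
            for (int mj = 0; mj < 4; ++mj) {
              const double wjk = wk * w2[4 * j + mj];
              const size_t ojk = ok + (size_t)(b2[j] + mj) * n1;
              for (int mi = 0; mi < 4; ++mi)
                acc += wjk * w1[4 * i + mi] * cc[ojk + b1[i] + mi];
            }
          }
          out[idx] = acc;
        }
  }
  field.attr("dim") = IntegerVector::create(d[0], d[1], d[2], 3);
  return field;
}

// Adjoint: scatter a per-voxel field gradient back onto control points.
// [[Rcpp::export]]
NumericVector bspline_adjoint_cpp(NumericVector grad, IntegerVector ncp,
                                  IntegerVector dims, NumericVector sp) {
  const int d[3] = { dims[0], dims[1], dims[2] };
  const int n1 = ncp[0], n2 = ncp[1], n3 = ncp[2];
  const size_t nvox = (size_t)d[0] * d[1] * d[2];
  const size_t ncoef = (size_t)n1 * n2 * n3;
  NumericVector cg(ncoef * 3);
  std::vector<int> b1, b2, b3;
  std::vector<double> w1, w2, w3;
  bsp_weights(d[0], sp[0], b1, w1);
  bsp_weights(d[1], sp[1], b2, w2);
  bsp_weights(d[2], sp[2], b3, w3);
  for (int comp = 0; comp < 3; ++comp) {
    const double* g = grad.begin() + comp * nvox;
    double* cc = cg.begin() + comp * ncoef;
    size_t idx = 0;
    for (int k = 0; k < d[2]; ++k)
      for (int j = 0; j < d[1]; ++j)
        for (int i = 0; i < d[0]; ++i, ++idx) {
          const double gv = g[idx];
          if (gv == 0) continue;
          for (int mk = 0; mk < 4; ++mk) {
            const double wk = w3[4 * k + mk];
            const size_t ok = (size_t)(b3[k] + mk) * n1 * n2;
            for (int mj = 0; mj < 4; ++mj) {
              const double wjk = wk * w2[4 * j + mj];
              const size_t ojk = ok + (size_t)(b2[j] + mj) * n1;
              for (int mi = 0; mi < 4; ++mi)
                cc[ojk + b1[i] + mi] += gv * wjk * w1[4 * i + mi];
            }
          }
        }
  }
  cg.attr("dim") = IntegerVector::create(n1, n2, n3, 3);
  return cg;
}

// ---------------------------------------------------------------------------
// Gamma index: per reference voxel, min over candidate offsets (sorted by
// distance, early break) of sqrt(dist^2/DTA^2 + dD^2/(tol*Dnorm)^2).
// Candidates are fractional-voxel offsets within radius 3*DTA.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector gamma_map_cpp(NumericVector ref, NumericVector eval,
                            IntegerVector dims, NumericVector spacing,
                            double dta, double tol_abs, double cutoff_abs,
                            IntegerVector refine) {
  const int d[3] = { dims[0], dims[1], dims[2] };
  const size_t n = (size_t)d[0] * d[1] * d[2];
  NumericVector gam(n);
  // build candidate list
  struct Cand { double o1, o2, o3, dist2; };
  std::vector<Cand> cands;
  const double rad = 3.0 * dta;
  int m[3];
  double step[3];
  for (int a = 0; a < 3; ++a) {
    step[a] = spacing[a] / refine[a];
    m[a] = (int)std::floor(rad / step[a]);
  }
  for (int k = -m[2]; k <= m[2]; ++k)
    for (int j = -m[1]; j <= m[1]; ++j)
      for (int i = -m[0]; i <= m[0]; ++i) {
        const double dz = i * step[0], dy = j * step[1], dx = k * step[2];
        const double dist2 = dz * dz + dy * dy + dx * dx;
        if (dist2 > rad * rad) continue;
        cands.push_back({ (double)i / refine[0], (double)j / refine[1],
                          (double)k / refine[2], dist2 });
      }
  std::sort(cands.begin(), cands.end(),
            [](const Cand& a, const Cand& b) { return a.dist2 < b.dist2; });
  const double dta2 = dta * dta, tol2 = tol_abs * tol_abs;
  const double* ev = eval.begin();
  size_t idx = 0;
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i, ++idx) {
        const double Dr = ref[idx];
        if (Dr < cutoff_abs) { gam[idx] = NA_REAL; continue; }
        double best = R_PosInf;
        for (const Cand& c : cands) {
          const double dterm = c.dist2 / dta2;
          if (dterm >= best) break;
          const double x1 = i + c.o1, x2 = j + c.o2, x3 = k + c.o3;
          if (x1 < 0 || x1 > d[0] - 1 || x2 < 0 || x2 > d[1] - 1 ||
              x3 < 0 || x3 > d[2] - 1)
            continue;
          const double De = tri_sample(ev, d, x1, x2, x3);
          const double g = dterm + (De - Dr) * (De - Dr) / tol2;
          if (g < best) best = g;
        }
        gam[idx] = std::sqrt(best);
      }
  gam.attr("dim") = dims;
  return gam;
}

// ---------------------------------------------------------------------------
// 6-connected 3D component labeling.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims) {
  const int d[3] = { dims[0], dims[1], dims[2] };
  const size_t n = (size_t)d[0] * d[1] * d[2];
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<size_t> stack;
  for (size_t s0 = 0; s0 < n; ++s0) {
    if (!mask[s0] || lab[s0] != 0) continue;
    ++next;
    stack.push_back(s0);
    lab[s0] = next;
    while (!stack.empty()) {
      const size_t s = stack.back();
      stack.pop_back();
      const int i = s % d[0];
      const int j = (s / d[0]) % d[1];
      const int k = s / ((size_t)d[0] * d[1]);
      const int di[6] = { -1, 1, 0, 0, 0, 0 };
      const int dj[6] = { 0, 0, -1, 1, 0, 0 };
      const int dk[6] = { 0, 0, 0, 0, -1, 1 };
      for (int q = 0; q < 6; ++q) {
        const int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || ii >= d[0] || jj < 0 || jj >= d[1] ||
            kk < 0 || kk >= d[2]) continue;
        const size_t t = ii + d[0] * ((size_t)jj + d[1] * kk);
        if (mask[t] && lab[t] == 0) { lab[t] = next; stack.push_back(t); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// ---------------------------------------------------------------------------
// Radiological depth of each pixel of a 2D slice along a beam direction:
// march upstream (-dir) in steps of step_mm, summing relative density.
// dir is (row, col) in mm-world, unit length.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix beam_depth_cpp(const NumericMatrix& dens, double dir_r,
                             double dir_c, double sp_r, double sp_c,
                             double step_mm) {
  const int H = dens.nrow(), W = dens.ncol();
  NumericMatrix depth(H, W);
  const int d2[3] = { H, W, 1 };
  std::vector<double> v(dens.begin(), dens.end());
  const double ext_r = H * sp_r, ext_c = W * sp_c;
  const int maxsteps = (int)std::ceil(std::sqrt(ext_r * ext_r + ext_c * ext_c) /
                                      step_mm) + 2;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double pr = r * sp_r, pc = c * sp_c;
      double acc = 0;
      for (int s = 0; s < maxsteps; ++s) {
        pr -= dir_r * step_mm;
        pc -= dir_c * step_mm;
        const double ur = pr / sp_r, uc = pc / sp_c;
        if (ur < 0 || ur > H - 1 || uc < 0 || uc > W - 1) break;
        acc += tri_sample(v.data(), d2, ur, uc, 0.0) * step_mm;
      }
      depth(r, c) = acc;
    }
  return depth;
}
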