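#include <Rcpp.h>
using namespace Rcpp;

// Edge-clamped bilinear sample of img at (r, c) in 0-based pixel coords.
static inline double sample_bilinear(const NumericMatrix& img, double r, double c) {
  const int nr = img.nrow(), nc = img.ncol();
  if (r < 0) r = 0; else if (r > nr - 1) r = nr - 1;
  if (c < 0) c = 0; else if (c > nc - 1) c = nc - 1;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  int r1 = r0 + 1 < nr ? r0 + 1 : r0;
  int c1 = c0 + 1 < nc ? c0 + 1 : c0;
  double fr = r - r0, fc = c - c0;
  return (1 - fr) * ((1 - fc) * img(r0, c0) + fc * img(r0, c1)) +
         fr       * ((1 - fc) * img(r1, c0) + fc * img(r1, c1));
}

// Pull-back warp: out(p) = img(p + d(p)), bilinear, edge clamp.
// [[Rcpp::export]]
NumericMatrix cpp_warp_bilinear(const NumericMatrix& img,
                                const NumericMatrix& dr,
                                const NumericMatrix& dc) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = sample_bilinear(img, i + dr(i, j), j + dc(i, j));
  return out;
}

// Pull-back warp with nearest-neighbour sampling (labels / masks).
// [[Rcpp::export]]
NumericMatrix cpp_warp_nearest(const NumericMatrix& img,
                               const NumericMatrix& dr,
                               const NumericMatrix& dc) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double r = i + dr(i, j), c = j + dc(i, j);
      int ri = (int)std::lround(r), ci = (int)std::lround(c);
      if (ri < 0) ri = 0; else if (ri > nr - 1) ri = nr - 1;
      if (ci < 0) ci = 0; else if (ci > nc - 1) ci = nc - 1;
      out(i, j) = img(ri, ci);
    }
  return out;
}

// Separable Gaussian smoothing, edge-clamped (replicate) boundary.
// Kernel truncated at 3 sigma. sigma <= 0 returns a copy.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_smooth(const NumericMatrix& img, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  if (sigma <= 0) {
    std::copy(img.begin(), img.end(), out.begin());
    return out;
  }
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * rad + 1);
  double s = 0;
  for (int t = -rad; t <= rad; ++t) {
    k[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += k[t + rad];
  }
  for (double& w : k) w /= s;
  NumericMatrix tmp(nr, nc);
  // rows (vertical pass)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0;
      for (int t = -rad; t <= rad; ++t) {
        int ii = i + t;
        if (ii < 0) ii = 0; else if (ii > nr - 1) ii = nr - 1;
        acc += k[t + rad] * img(ii, j);
      }
      tmp(i, j) = acc;
    }
  // cols (horizontal pass)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0;
      for (int t = -rad; t <= rad; ++t) {
        int jj = j + t;
        if (jj < 0) jj = 0; else if (jj > nc - 1) jj = nc - 1;
        acc += k[t + rad] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  return out;
}

// Field composition (f o g)(p) = g(p) + f(p + g(p)), bilinear sampling of f.
// [[Rcpp::export]]
List cpp_compose(const NumericMatrix& fr, const NumericMatrix& fc,
                 const NumericMatrix& gr, const NumericMatrix& gc) {
  const int nr = fr.nrow(), nc = fr.ncol();
  NumericMatrix hr(nr, nc), hc(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double r = i + gr(i, j), c = j + gc(i, j);
      hr(i, j) = gr(i, j) + sample_bilinear(fr, r, c);
      hc(i, j) = gc(i, j) + sample_bilinear(fc, r, c);
    }
  return List::create(_["dr"] = hr, _["dc"] = hc);
}

// Exponential of a stationary velocity field by scaling and squaring.
// [[Rcpp::export]]
List cpp_field_exp(const NumericMatrix& vr, const NumericMatrix& vc,
                   int n_steps) {
  const int nr = vr.nrow(), nc = vr.ncol();
  double scale = 1.0 / std::pow(2.0, n_steps);
  NumericMatrix ur(nr, nc), uc(nr, nc);
  for (int t = 0; t < nr * nc; ++t) {
    ur[t] = vr[t] * scale;
    uc[t] = vc[t] * scale;
  }
  for (int s = 0; s < n_steps; ++s) {
    List h = cpp_compose(ur, uc, ur, uc);
    ur = as<NumericMatrix>(h["dr"]);
    uc = as<NumericMatrix>(h["dc"]);
  }
  return List::create(_["dr"] = ur, _["dc"] = uc);
}

// Bilinear resize with pixel-center alignment (used for pyramid transfer).
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(const NumericMatrix& img, int nr2, int nc2) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr2, nc2);
  double sr = (double)nr / nr2, sc = (double)nc / nc2;
  for (int j = 0; j < nc2; ++j)
    for (int i = 0; i < nr2; ++i)
      out(i, j) = sample_bilinear(img, (i + 0.5) * sr - 0.5, (j + 0.5) * sc - 0.5);
  return out;
}

// Central-difference gradients, one-sided at the border (matches the R
// helper image_gradient()).
static void grad2d(const NumericMatrix& img, NumericMatrix& gr, NumericMatrix& gc) {
  const int nr = img.nrow(), nc = img.ncol();
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (nr >= 3) {
        if (i == 0) gr(i, j) = img(1, j) - img(0, j);
        else if (i == nr - 1) gr(i, j) = img(nr - 1, j) - img(nr - 2, j);
        else gr(i, j) = (img(i + 1, j) - img(i - 1, j)) / 2.0;
      } else gr(i, j) = 0;
      if (nc >= 3) {
        if (j == 0) gc(i, j) = img(i, 1) - img(i, 0);
        else if (j == nc - 1) gc(i, j) = img(i, nc - 1) - img(i, nc - 2);
        else gc(i, j) = (img(i, j + 1) - img(i, j - 1)) / 2.0;
      } else gc(i, j) = 0;
    }
  }
}

// Local correlation coefficient within a Gaussian window, regularised the
// same way as the R helper local_corr().
static NumericMatrix local_corr_cpp(const NumericMatrix& a, const NumericMatrix& b,
                                    double sigma) {
  NumericMatrix mu_a = cpp_gauss_smooth(a, sigma);
  NumericMatrix mu_b = cpp_gauss_smooth(b, sigma);
  const int n = a.nrow() * a.ncol();
  NumericMatrix a2(a.nrow(), a.ncol()), b2(a.nrow(), a.ncol()), ab(a.nrow(), a.ncol());
  for (int t = 0; t < n; ++t) {
    a2[t] = a[t] * a[t];
    b2[t] = b[t] * b[t];
    ab[t] = a[t] * b[t];
  }
  NumericMatrix va = cpp_gauss_smooth(a2, sigma);
  NumericMatrix vb = cpp_gauss_smooth(b2, sigma);
  NumericMatrix cab = cpp_gauss_smooth(ab, sigma);
  NumericMatrix out(a.nrow(), a.ncol());
  for (int t = 0; t < n; ++t) {
    double vva = va[t] - mu_a[t] * mu_a[t];
    double vvb = vb[t] - mu_b[t] * mu_b[t];
    if (vva < 0) vva = 0;
    if (vvb < 0) vvb = 0;
    out[t] = (cab[t] - mu_a[t] * mu_b[t]) / (std::sqrt(vva * vvb) + 1e-3);
  }
  return out;
}

NumericMatrix cpp_smooth_boxes(const NumericMatrix& img, double sigma);

// One pyramid level of the symmetric log-domain demons iteration with the
// polarity-corrected, correlation-weighted force (see the R-level docs).
// [[Rcpp::export]]
List cpp_demons_level(const NumericMatrix& f, const NumericMatrix& m,
                      NumericMatrix vr, NumericMatrix vc,
                      int iters, double sigma_fluid, double sigma_diffusion,
                      double lncc_window_sigma, int n_squaring_steps,
                      double step_scale) {
  const int nr = f.nrow(), nc = f.ncol();
  const int n = nr * nc;
  NumericMatrix gfr(nr, nc), gfc(nr, nc), gmr(nr, nc), gmc(nr, nc);
  grad2d(f, gfr, gfc);
  grad2d(m, gmr, gmc);
  NumericMatrix g2f(nr, nc), g2m(nr, nc);
  for (int t = 0; t < n; ++t) {
    g2f[t] = gfr[t] * gfr[t] + gfc[t] * gfc[t];
    g2m[t] = gmr[t] * gmr[t] + gmc[t] * gmc[t];
  }
  int bw = std::min(2, (std::min(nr, nc) - 1) / 2);
  NumericMatrix border(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      border(i, j) = (i < bw || i >= nr - bw || j < bw || j >= nc - bw) ? 0.0 : 1.0;
  const double tiny = 1e-9;
  NumericMatrix nvr(nr, nc), nvc(nr, nc), ur(nr, nc), uc(nr, nc);
  for (int it = 0; it < iters; ++it) {
    List ef = cpp_field_exp(vr, vc, n_squaring_steps);
    for (int t = 0; t < n; ++t) { nvr[t] = -vr[t]; nvc[t] = -vc[t]; }
    List eb = cpp_field_exp(nvr, nvc, n_squaring_steps);
    NumericMatrix wm = cpp_warp_bilinear(m, ef["dr"], ef["dc"]);
    NumericMatrix wf = cpp_warp_bilinear(f, eb["dr"], eb["dc"]);
    NumericMatrix r1 = local_corr_cpp(f, wm, lncc_window_sigma);
    NumericMatrix r2 = local_corr_cpp(m, wf, lncc_window_sigma);
    for (int t = 0; t < n; ++t) {
      double d1 = r1[t] * wm[t] - std::fabs(r1[t]) * f[t];
      double d2 = r2[t] * wf[t] - std::fabs(r2[t]) * m[t];
      double den1 = g2f[t] + d1 * d1 + tiny;
      double den2 = g2m[t] + d2 * d2 + tiny;
      ur[t] = 0.5 * ((-d1 * gfr[t] / den1) - (-d2 * gmr[t] / den2)) * border[t];
      uc[t] = 0.5 * ((-d1 * gfc[t] / den1) - (-d2 * gmc[t] / den2)) * border[t];
    }
    NumericMatrix sur = cpp_gauss_smooth(ur, sigma_fluid);
    NumericMatrix suc = cpp_gauss_smooth(uc, sigma_fluid);
    for (int t = 0; t < n; ++t) {
      nvr[t] = vr[t] + step_scale * sur[t];
      nvc[t] = vc[t] + step_scale * suc[t];
    }
    if (sigma_diffusion >= 8.0) {
      vr = cpp_smooth_boxes(nvr, sigma_diffusion);
      vc = cpp_smooth_boxes(nvc, sigma_diffusion);
    } else {
      vr = cpp_gauss_smooth(nvr, sigma_diffusion);
      vc = cpp_gauss_smooth(nvc, sigma_diffusion);
    }
  }
  return List::create(_["dr"] = vr, _["dc"] = vc);
}

// One edge-clamped 1D box pass along rows (vertical) or cols, width w (odd).
static void box_pass(std::vector<double>& x, std::vector<double>& buf,
                     std::vector<double>& out, int n, int w) {
  int r = (w - 1) / 2;
  // prefix sums in buf[1..n]
  buf[0] = 0;
  for (int i = 0; i < n; ++i) buf[i + 1] = buf[i] + x[i];
  for (int i = 0; i < n; ++i) {
    int lo = i - r, hi = i + r;
    int left = lo < 0 ? -lo : 0;
    int right = hi > n - 1 ? hi - (n - 1) : 0;
    if (lo < 0) lo = 0;
    if (hi > n - 1) hi = n - 1;
    out[i] = (buf[hi + 1] - buf[lo] + left * x[0] + right * x[n - 1]) / w;
  }
  for (int i = 0; i < n; ++i) x[i] = out[i];
}

// Gaussian-approximating smoothing by three cascaded box filters (edge
// clamped). Used for the large diffusion-regularisation widths in the
// demons loop, where an exact FIR kernel would dominate the runtime.
// [[Rcpp::export]]
NumericMatrix cpp_smooth_boxes(const NumericMatrix& img, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  const int nb = 5;
  double wi = std::sqrt(12.0 * sigma * sigma / nb + 1.0);
  int wl = (int)std::floor(wi);
  if (wl % 2 == 0) wl -= 1;
  int wu = wl + 2;
  double mi = (12.0 * sigma * sigma - nb * wl * wl - 4.0 * nb * wl - 3.0 * nb) /
              (-4.0 * wl - 4.0);
  int m = (int)std::lround(mi);
  if (m < 0) m = 0;
  if (m > nb) m = nb;
  NumericMatrix out(clone(img));
  std::vector<double> x(std::max(nr, nc)), buf(std::max(nr, nc) + 1),
      stage(std::max(nr, nc));
  for (int pass = 0; pass < nb; ++pass) {
    int w = pass < m ? wl : wu;
    if (w < 3) continue;
    for (int j = 0; j < nc; ++j) {           // vertical
      for (int i = 0; i < nr; ++i) x[i] = out(i, j);
      box_pass(x, buf, stage, nr, w);
      for (int i = 0; i < nr; ++i) out(i, j) = x[i];
    }
    for (int i = 0; i < nr; ++i) {           // horizontal
      for (int j = 0; j < nc; ++j) x[j] = out(i, j);
      box_pass(x, buf, stage, nc, w);
      for (int j = 0; j < nc; ++j) out(i, j) = x[j];
    }
  }
  return out;
}
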