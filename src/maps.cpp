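// Discrete-grid kernels of the two-state attention model.
//
// All maps live on an H x W pixel grid; pixel (x, y) has its center at the
// integer coordinates (x, y), x = 0..W-1 (column), y = 0..H-1 (row). Gaussian
// kernels are evaluated un-truncated at pixel centers and the resulting map is
// renormalized within the image, so every returned distribution is a proper
// probability mass function over pixels.
//
// Axis separability (diagonal covariances) is exploited throughout: a 2-D
// kernel at (px, py) is the outer product of two 1-D kernels, so normalizing
// the local map costs O(H + W) and only the saliency-weighted global map needs
// a full O(H W) pass.

#include <Rcpp.h>
using namespace Rcpp;

static const double LOG_FLOOR = -690.77552789821368;  // log(1e-300)

// 1-D Gaussian density at integer offsets i - center, i = 0..n-1, variance v;
// optionally the factor g_i = d log n_i / d log v = (d^2 / v - 1) / 2.
static void gauss_axis(int n, double center, double v,
                       std::vector<double> &dens, std::vector<double> *gfac) {
  const double norm = 1.0 / std::sqrt(2.0 * M_PI * v);
  dens.resize(n);
  if (gfac) gfac->resize(n);
  for (int i = 0; i < n; ++i) {
    const double d = i - center;
    const double q = d * d / v;
    dens[i] = norm * std::exp(-0.5 * q);
    if (gfac) (*gfac)[i] = 0.5 * (q - 1.0);
  }
}

static double gauss1(double d, double v) {
  return std::exp(-0.5 * d * d / v) / std::sqrt(2.0 * M_PI * v);
}

// [[Rcpp::export]]
NumericMatrix cpp_local_map(int H, int W, double px, double py,
                            double ex, double ey) {
  std::vector<double> nx, ny;
  gauss_axis(W, px, ex, nx, nullptr);
  gauss_axis(H, py, ey, ny, nullptr);
  double sx = 0.0, sy = 0.0;
  for (int i = 0; i < W; ++i) sx += nx[i];
  for (int j = 0; j < H; ++j) sy += ny[j];
  const double Z = sx * sy;
  NumericMatrix out(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      out(y, x) = nx[x] * ny[y] / Z;
  return out;
}

// Raw (unnormalized) global-attention map max(s * n_xi - n_eps, 0) and its
// total mass; normalization and the degenerate-map error live on the R side.
// [[Rcpp::export]]
List cpp_global_map(NumericMatrix s, double px, double py,
                    double ex, double ey, double xx, double xy) {
  const int H = s.nrow(), W = s.ncol();
  std::vector<double> nxx, nxy, nex, ney;
  gauss_axis(W, px, xx, nxx, nullptr);
  gauss_axis(H, py, xy, nxy, nullptr);
  gauss_axis(W, px, ex, nex, nullptr);
  gauss_axis(H, py, ey, ney, nullptr);
  NumericMatrix out(H, W);
  double total = 0.0;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      double v = s(y, x) * nxx[x] * nxy[y] - nex[x] * ney[y];
      if (v < 0.0) v = 0.0;
      out(y, x) = v;
      total += v;
    }
  }
  return List::create(_["map"] = out, _["total"] = total);
}

// Raw local-saliency map s * n_xi and its total mass.
// [[Rcpp::export]]
List cpp_local_saliency_map(NumericMatrix s, double px, double py,
                            double xx, double xy) {
  const int H = s.nrow(), W = s.ncol();
  std::vector<double> nxx, nxy;
  gauss_axis(W, px, xx, nxx, nullptr);
  gauss_axis(H, py, xy, nxy, nullptr);
  NumericMatrix out(H, W);
  double total = 0.0;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      const double v = s(y, x) * nxx[x] * nxy[y];
      out(y, x) = v;
      total += v;
    }
  }
  return List::create(_["map"] = out, _["total"] = total);
}

// log p_local(cur | prev) for a batch of saccades (normalizer is separable).
// prev, cur: n x 2 matrices of (x, y).
// [[Rcpp::export]]
NumericVector cpp_local_logdens(NumericMatrix prev, NumericMatrix cur,
                                int H, int W, double ex, double ey) {
  const int n = prev.nrow();
  NumericVector out(n);
  std::vector<double> nx, ny;
  for (int i = 0; i < n; ++i) {
    gauss_axis(W, prev(i, 0), ex, nx, nullptr);
    gauss_axis(H, prev(i, 1), ey, ny, nullptr);
    double sx = 0.0, sy = 0.0;
    for (int k = 0; k < W; ++k) sx += nx[k];
    for (int k = 0; k < H; ++k) sy += ny[k];
    const double dx = cur(i, 0) - prev(i, 0), dy = cur(i, 1) - prev(i, 1);
    out[i] = std::log(gauss1(dx, ex)) + std::log(gauss1(dy, ey)) -
             std::log(sx) - std::log(sy);
  }
  return out;
}

// log p_global(cur | prev) for a batch of saccades over per-image saliency
// maps. img holds 0-based indices into s_list. A saccade landing on a pixel
// clamped to zero gets the floored log-probability and is counted in n_zero;
// an all-zero map marks the whole batch degenerate.
// [[Rcpp::export]]
List cpp_global_logdens(List s_list, IntegerVector img,
                        NumericMatrix prev, NumericMatrix cur,
                        double ex, double ey, double xx, double xy) {
  const int n = prev.nrow();
  NumericVector out(n);
  int n_zero = 0;
  bool degenerate = false;
  std::vector<double> nxx, nxy, nex, ney;
  for (int i = 0; i < n; ++i) {
    NumericMatrix s = s_list[img[i]];
    const int H = s.nrow(), W = s.ncol();
    const double px = prev(i, 0), py = prev(i, 1);
    gauss_axis(W, px, xx, nxx, nullptr);
    gauss_axis(H, py, xy, nxy, nullptr);
    gauss_axis(W, px, ex, nex, nullptr);
    gauss_axis(H, py, ey, ney, nullptr);
    double Z = 0.0;
    for (int x = 0; x < W; ++x) {
      const double a = nxx[x], b = nex[x];
      for (int y = 0; y < H; ++y) {
        const double v = s(y, x) * a * nxy[y] - b * ney[y];
        if (v > 0.0) Z += v;
      }
    }
    if (Z <= 0.0) {
      degenerate = true;
      out[i] = R_NegInf;
      continue;
    }
    const int cx = (int)cur(i, 0), cy = (int)cur(i, 1);
    const double num = s(cy, cx) * nxx[cx] * nxy[cy] - nex[cx] * ney[cy];
    if (num <= 0.0) {
      out[i] = LOG_FLOOR;
      ++n_zero;
    } else {
      out[i] = std::log(num) - std::log(Z);
    }
  }
  return List::create(_["logp"] = out, _["n_zero"] = n_zero,
                      _["degenerate"] = degenerate);
}

// Log conditional likelihood of the length scales given the mode tags, and
// its gradient in (log ex, log ey, log xx, log xy):
//   sum_{gamma=1} log p_local(z_t) + sum_{gamma=0} log p_global(z_t).
// Saccades whose global numerator is clamped to zero contribute the constant
// floor and no gradient (the clamp is flat there).
// [[Rcpp::export]]
List cpp_scales_loglik_grad(List s_list, IntegerVector img,
                            NumericMatrix prev, NumericMatrix cur,
                            IntegerVector gamma, int H, int W,
                            double ex, double ey, double xx, double xy,
                            bool want_grad) {
  const int n = prev.nrow();
  double val = 0.0;
  NumericVector grad(4);
  int n_zero = 0;
  std::vector<double> nxx, nxy, nex, ney, gxx, gxy, gex, gey;

  for (int i = 0; i < n; ++i) {
    const double px = prev(i, 0), py = prev(i, 1);
    const double dx = cur(i, 0) - px, dy = cur(i, 1) - py;
    if (gamma[i] == 1) {  // local step: separable in each axis
      gauss_axis(W, px, ex, nex, want_grad ? &gex : nullptr);
      gauss_axis(H, py, ey, ney, want_grad ? &gey : nullptr);
      double sx = 0.0, sy = 0.0, sgx = 0.0, sgy = 0.0;
      for (int k = 0; k < W; ++k) { sx += nex[k]; if (want_grad) sgx += nex[k] * gex[k]; }
      for (int k = 0; k < H; ++k) { sy += ney[k]; if (want_grad) sgy += ney[k] * gey[k]; }
      val += std::log(gauss1(dx, ex)) + std::log(gauss1(dy, ey)) -
             std::log(sx) - std::log(sy);
      if (want_grad) {
        grad[0] += 0.5 * (dx * dx / ex - 1.0) - sgx / sx;
        grad[1] += 0.5 * (dy * dy / ey - 1.0) - sgy / sy;
      }
      // the state must keep the global map proper at every saccade (the
      // mode update needs it), so check positivity here too; early exit on
      // the first active pixel keeps this near-free in the typical case
      NumericMatrix s = s_list[img[i]];
      const int Hi = s.nrow(), Wi = s.ncol();
      gauss_axis(Wi, px, xx, nxx, nullptr);
      gauss_axis(Hi, py, xy, nxy, nullptr);
      bool any_pos = false;
      for (int x = 0; x < Wi && !any_pos; ++x) {
        const double a = nxx[x], b = nex[x];
        for (int y = 0; y < Hi; ++y)
          if (s(y, x) * a * nxy[y] - b * ney[y] > 0.0) { any_pos = true; break; }
      }
      if (!any_pos)
        return List::create(_["value"] = R_NegInf, _["grad"] = grad,
                            _["degenerate"] = true, _["n_zero"] = n_zero);
    } else {              // global step: full-grid pass over the active set
      NumericMatrix s = s_list[img[i]];
      const int Hi = s.nrow(), Wi = s.ncol();
      gauss_axis(Wi, px, xx, nxx, want_grad ? &gxx : nullptr);
      gauss_axis(Hi, py, xy, nxy, want_grad ? &gxy : nullptr);
      gauss_axis(Wi, px, ex, nex, want_grad ? &gex : nullptr);
      gauss_axis(Hi, py, ey, ney, want_grad ? &gey : nullptr);
      double Z = 0.0, dZ0 = 0.0, dZ1 = 0.0, dZ2 = 0.0, dZ3 = 0.0;
      for (int x = 0; x < Wi; ++x) {
        const double a = nxx[x], b = nex[x];
        for (int y = 0; y < Hi; ++y) {
          const double t1 = s(y, x) * a * nxy[y];
          const double t2 = b * ney[y];
          const double v = t1 - t2;
          if (v > 0.0) {
            Z += v;
            if (want_grad) {
              dZ2 += t1 * gxx[x];
              dZ3 += t1 * gxy[y];
              dZ0 -= t2 * gex[x];
              dZ1 -= t2 * gey[y];
            }
          }
        }
      }
      if (Z <= 0.0)
        return List::create(_["value"] = R_NegInf, _["grad"] = grad,
                            _["degenerate"] = true, _["n_zero"] = n_zero);
      const int cx = (int)cur(i, 0), cy = (int)cur(i, 1);
      const double t1 = s(cy, cx) * nxx[cx] * nxy[cy];
      const double t2 = nex[cx] * ney[cy];
      const double num = t1 - t2;
      if (num <= 0.0) {
        val += LOG_FLOOR;  // clamped data point: flat contribution
        ++n_zero;
      } else {
        val += std::log(num) - std::log(Z);
        if (want_grad) {
          grad[2] += t1 * gxx[cx] / num - dZ2 / Z;
          grad[3] += t1 * gxy[cy] / num - dZ3 / Z;
          grad[0] += -t2 * gex[cx] / num - dZ0 / Z;
          grad[1] += -t2 * gey[cy] / num - dZ1 / Z;
        }
      }
    }
  }
  return List::create(_["value"] = val, _["grad"] = grad,
                      _["degenerate"] = false, _["n_zero"] = n_zero);
}

// Marginal (label-collapsed) log conditional of the length scales given the
// link values, and its gradient in (log ex, log ey, log xx, log xy):
//   sum_t log( rho_t p_local(z_t) + (1 - rho_t) p_global(z_t) ),
// supplied as log rho_t / log(1 - rho_t) for saturation safety. The gradient
// of each term is the posterior-label-weighted mix of the component
// gradients: q_t d(log p_local) + (1 - q_t) d(log p_global), with
// q_t = rho_t p_local / (rho_t p_local + (1 - rho_t) p_global).
// [[Rcpp::export]]
List cpp_scales_marginal_grad(List s_list, IntegerVector img,
                              NumericMatrix prev, NumericMatrix cur,
                              NumericVector logrho, NumericVector log1mrho,
                              double ex, double ey, double xx, double xy,
                              bool want_grad) {
  const int n = prev.nrow();
  double val = 0.0;
  NumericVector grad(4);
  // per-saccade component values and gradients, returned so the caller can
  // reuse them (they depend on the scales only, not on the gate)
  NumericVector vllo(n), vglo(n);
  NumericMatrix mdllo(n, 2), mdglo(n, 4);
  std::vector<double> nxx, nxy, nex, ney, gxx, gxy, gex, gey;

  for (int i = 0; i < n; ++i) {
    NumericMatrix s = s_list[img[i]];
    const int Hi = s.nrow(), Wi = s.ncol();
    const double px = prev(i, 0), py = prev(i, 1);
    const double dx = cur(i, 0) - px, dy = cur(i, 1) - py;
    gauss_axis(Wi, px, xx, nxx, want_grad ? &gxx : nullptr);
    gauss_axis(Hi, py, xy, nxy, want_grad ? &gxy : nullptr);
    gauss_axis(Wi, px, ex, nex, want_grad ? &gex : nullptr);
    gauss_axis(Hi, py, ey, ney, want_grad ? &gey : nullptr);

    // local component: separable normalizer
    double sx = 0.0, sy = 0.0, sgx = 0.0, sgy = 0.0;
    for (int k = 0; k < Wi; ++k) { sx += nex[k]; if (want_grad) sgx += nex[k] * gex[k]; }
    for (int k = 0; k < Hi; ++k) { sy += ney[k]; if (want_grad) sgy += ney[k] * gey[k]; }
    const double llo = std::log(gauss1(dx, ex)) + std::log(gauss1(dy, ey)) -
                       std::log(sx) - std::log(sy);
    const double dllo_ex = want_grad ? 0.5 * (dx * dx / ex - 1.0) - sgx / sx : 0.0;
    const double dllo_ey = want_grad ? 0.5 * (dy * dy / ey - 1.0) - sgy / sy : 0.0;

    // global component: clamped grid pass
    double Z = 0.0, dZ0 = 0.0, dZ1 = 0.0, dZ2 = 0.0, dZ3 = 0.0;
    for (int x = 0; x < Wi; ++x) {
      const double a = nxx[x], b = nex[x];
      for (int y = 0; y < Hi; ++y) {
        const double t1 = s(y, x) * a * nxy[y];
        const double t2 = b * ney[y];
        const double v = t1 - t2;
        if (v > 0.0) {
          Z += v;
          if (want_grad) {
            dZ2 += t1 * gxx[x];
            dZ3 += t1 * gxy[y];
            dZ0 -= t2 * gex[x];
            dZ1 -= t2 * gey[y];
          }
        }
      }
    }
    if (Z <= 0.0)
      return List::create(_["value"] = R_NegInf, _["grad"] = grad,
                          _["degenerate"] = true);
    const int cx = (int)cur(i, 0), cy = (int)cur(i, 1);
    const double t1 = s(cy, cx) * nxx[cx] * nxy[cy];
    const double t2 = nex[cx] * ney[cy];
    const double num = t1 - t2;
    double glo, dglo_ex = 0.0, dglo_ey = 0.0, dglo_xx = 0.0, dglo_xy = 0.0;
    bool clamped = (num <= 0.0);
    if (clamped) {
      glo = LOG_FLOOR;
    } else {
      glo = std::log(num) - std::log(Z);
      if (want_grad) {
        dglo_xx = t1 * gxx[cx] / num - dZ2 / Z;
        dglo_xy = t1 * gxy[cy] / num - dZ3 / Z;
        dglo_ex = -t2 * gex[cx] / num - dZ0 / Z;
        dglo_ey = -t2 * gey[cy] / num - dZ1 / Z;
      }
    }

    // log-sum-exp mixture and soft label weight
    const double aa = logrho[i] + llo, bb = log1mrho[i] + glo;
    const double m = aa > bb ? aa : bb;
    const double lmix = m + std::log(std::exp(aa - m) + std::exp(bb - m));
    val += lmix;
    vllo[i] = llo;
    vglo[i] = glo;
    if (want_grad) {
      // guard the clamp kink: dglo can overflow there while its weight is
      // zero, and 0 * Inf would poison the gradient
      if (!std::isfinite(dglo_ex) || !std::isfinite(dglo_ey) ||
          !std::isfinite(dglo_xx) || !std::isfinite(dglo_xy)) {
        dglo_ex = dglo_ey = dglo_xx = dglo_xy = 0.0;
        clamped = true;
      }
      mdllo(i, 0) = dllo_ex;
      mdllo(i, 1) = dllo_ey;
      mdglo(i, 0) = dglo_ex;
      mdglo(i, 1) = dglo_ey;
      mdglo(i, 2) = dglo_xx;
      mdglo(i, 3) = dglo_xy;
      const double q = std::exp(aa - lmix);
      const double q1 = clamped ? 0.0 : 1.0 - q;
      grad[0] += q * dllo_ex;
      grad[1] += q * dllo_ey;
      if (q1 > 0.0) {
        grad[0] += q1 * dglo_ex;
        grad[1] += q1 * dglo_ey;
        grad[2] += q1 * dglo_xx;
        grad[3] += q1 * dglo_xy;
      }
    }
  }
  return List::create(_["value"] = val, _["grad"] = grad,
                      _["degenerate"] = false, _["llo"] = vllo,
                      _["glo"] = vglo, _["dllo"] = mdllo, _["dglo"] = mdglo);
}

// Same contract for the one-mode local-saliency variant, whose only scale
// parameters are (xx, xy): sum_t log[s(z_t) n_xi(z_t) / sum_z s n_xi].
// [[Rcpp::export]]
List cpp_localsal_loglik_grad(List s_list, IntegerVector img,
                              NumericMatrix prev, NumericMatrix cur,
                              double xx, double xy, bool want_grad) {
  const int n = prev.nrow();
  double val = 0.0;
  NumericVector grad(2);
  std::vector<double> nxx, nxy, gxx, gxy;
  for (int i = 0; i < n; ++i) {
    NumericMatrix s = s_list[img[i]];
    const int Hi = s.nrow(), Wi = s.ncol();
    const double px = prev(i, 0), py = prev(i, 1);
    gauss_axis(Wi, px, xx, nxx, want_grad ? &gxx : nullptr);
    gauss_axis(Hi, py, xy, nxy, want_grad ? &gxy : nullptr);
    double Z = 0.0, dZx = 0.0, dZy = 0.0;
    for (int x = 0; x < Wi; ++x) {
      const double a = nxx[x];
      for (int y = 0; y < Hi; ++y) {
        const double v = s(y, x) * a * nxy[y];
        Z += v;
        if (want_grad) {
          dZx += v * gxx[x];
          dZy += v * gxy[y];
        }
      }
    }
    if (Z <= 0.0)
      return List::create(_["value"] = R_NegInf, _["grad"] = grad,
                          _["degenerate"] = true);
    const int cx = (int)cur(i, 0), cy = (int)cur(i, 1);
    const double num = s(cy, cx) * nxx[cx] * nxy[cy];
    if (num <= 0.0) {
      val += LOG_FLOOR;
    } else {
      val += std::log(num) - std::log(Z);
      if (want_grad) {
        grad[0] += gxx[cx] - dZx / Z;
        grad[1] += gxy[cy] - dZy / Z;
      }
    }
  }
  return List::create(_["value"] = val, _["grad"] = grad,
                      _["degenerate"] = false);
}
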