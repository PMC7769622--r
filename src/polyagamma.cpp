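// Exact Devroye-type sampler for the Polya-Gamma distribution PG(1, c).
//
// PG(1, c) arises as the augmentation law that renders a Bernoulli-logistic
// likelihood conditionally Gaussian in its linear parameters:
//   sigma(f)^g (1 - sigma(f))^(1-g) = 2^-1 exp((g - 1/2) f) E_w[exp(-w f^2 / 2)],
// with w ~ PG(1, 0) tilted to PG(1, f). The sampler below draws from the
// Jacobi J*(1, z) law by the alternating-series rejection scheme and rescales,
// using the identity PG(1, c) = J*(1, |c| / 2) / 4.
//
// Useful moment for validation: E[PG(1, c)] = tanh(c / 2) / (2 c), = 1/4 at 0.

#include <Rcpp.h>
using namespace Rcpp;

static const double TRUNC = 0.64;  // series switch point t of the J* density

// n-th coefficient a_n(x) of the alternating series for the J*(1, 0) density
static double a_coef(int n, double x) {
  const double np5 = n + 0.5;
  if (x > TRUNC)
    return M_PI * np5 * std::exp(-np5 * np5 * M_PI * M_PI * 0.5 * x);
  return M_PI * np5 * std::pow(2.0 / (M_PI * x), 1.5) *
         std::exp(-2.0 * np5 * np5 / x);
}

// CDF at x of the inverse-Gaussian IG(mu = 1/z, lambda = 1); valid at z = 0
static double pigauss(double x, double z) {
  const double rsx = 1.0 / std::sqrt(x);
  const double b = rsx * (x * z - 1.0);
  const double a = -rsx * (x * z + 1.0);
  return R::pnorm(b, 0.0, 1.0, 1, 0) +
         std::exp(2.0 * z + R::pnorm(a, 0.0, 1.0, 1, 1));
}

// Draw from IG(mu = 1/z, lambda = 1) truncated to (0, t]
static double rtigauss(double z, double t) {
  z = std::fabs(z);
  double X;
  if (z < 1.0 / t) {  // mu > t: rejection from a truncated inverse-chi-square
    double alpha = 0.0;
    do {
      double E1, E2;
      do {
        E1 = R::exp_rand();
        E2 = R::exp_rand();
      } while (E1 * E1 > 2.0 * E2 / t);
      X = t / ((1.0 + t * E1) * (1.0 + t * E1));
      alpha = std::exp(-0.5 * z * z * X);
    } while (R::unif_rand() > alpha);
  } else {            // mu <= t: standard IG draw, retry until inside (0, t]
    const double mu = 1.0 / z;
    do {
      double Y = R::norm_rand();
      Y *= Y;
      const double muY = mu * Y;
      X = mu + 0.5 * mu * muY - 0.5 * mu * std::sqrt(4.0 * muY + muY * muY);
      if (R::unif_rand() > mu / (mu + X)) X = mu * mu / X;
    } while (X > t);
  }
  return X;
}

static double rpg1(double c) {
  const double z = 0.5 * std::fabs(c);
  const double K = M_PI * M_PI * 0.125 + 0.5 * z * z;
  const double p = (M_PI / (2.0 * K)) * std::exp(-K * TRUNC);
  const double q = 2.0 * std::exp(-z) * pigauss(TRUNC, z);
  const double ratio = p / (p + q);

  for (;;) {
    double X;
    if (R::unif_rand() < ratio)
      X = TRUNC + R::exp_rand() / K;    // exponential tail, right of t
    else
      X = rtigauss(z, TRUNC);           // truncated inverse-Gaussian body
    // squeeze acceptance by the alternating partial sums
    double S = a_coef(0, X);
    const double Y = R::unif_rand() * S;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        S -= a_coef(n, X);
        if (Y <= S) return 0.25 * X;    // accept
      } else {
        S += a_coef(n, X);
        if (Y > S) break;               // reject, redraw X
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_rpg(NumericVector c) {
  const int n = c.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(c[i]);
  return out;
}
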