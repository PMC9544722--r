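// Polya-Gamma PG(1, z) sampler (Devroye-type alternating-series method of
// Polson, Scott & Windle 2013), used for exact Gibbs updates of
// Bernoulli-logit latent values. Only the b = 1 case is needed here.

#include <Rcpp.h>
using namespace Rcpp;

static const double TRUNC = 0.64;
static const double PISQ8 = M_PI * M_PI / 8.0;

// coefficients of the alternating series for the J*(1, z) density
static inline double a_coef(int n, double x) {
  double np5 = n + 0.5;
  if (x <= TRUNC)
    return M_PI * np5 * std::pow(2.0 / (M_PI * x), 1.5) *
           std::exp(-2.0 * np5 * np5 / x);
  return M_PI * np5 * std::exp(-np5 * np5 * M_PI * M_PI * x / 2.0);
}

// inverse-Gaussian(1/z, 1) truncated to (0, TRUNC]; z may be 0
static double rtigauss(double z) {
  double mu = (z > 0) ? 1.0 / z : R_PosInf;
  double x;
  if (mu > TRUNC) {
    // rejection from the z = 0 (one-sided stable-like) proposal
    while (true) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / TRUNC);
      x = TRUNC / ((1.0 + TRUNC * e1) * (1.0 + TRUNC * e1));
      if (R::unif_rand() <= std::exp(-0.5 * z * z * x)) return x;
    }
  }
  // ordinary IG draws until one lands in the truncation region
  while (true) {
    double y = R::norm_rand();
    y = y * y;
    double muy = mu * y;
    x = mu + 0.5 * mu * muy -
        0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
    if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
    if (x <= TRUNC) return x;
  }
}

// one PG(1, z) draw: sample J*(1, z/2) by the two-piece proposal
// (truncated exponential right tail, truncated inverse-Gaussian left
// piece) with the alternating-series squeeze, then divide by 4
static double rpg1(double z) {
  z = std::fabs(z) * 0.5;
  double t = TRUNC;
  double fz = PISQ8 + 0.5 * z * z;
  // log-mass of the two proposal pieces (PSW mass_texpon)
  double b = std::sqrt(1.0 / t) * (t * z - 1.0);
  double a = -std::sqrt(1.0 / t) * (t * z + 1.0);
  double x0 = std::log(fz) + fz * t;
  double xb = x0 - z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + z + R::pnorm(a, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  double ratio = 1.0 / (1.0 + qdivp);
  while (true) {
    double x;
    if (R::unif_rand() < ratio)
      x = t + R::exp_rand() / fz;             // exponential right tail
    else
      x = rtigauss(z);
    // squeeze by the alternating series
    double s = a_coef(0, x);
    double y = R::unif_rand() * s;
    int n = 0;
    while (true) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return x / 4.0;
      } else {
        s += a_coef(n, x);
        if (y > s) break;                     // reject, draw a new x
      }
    }
  }
}

// [[Rcpp::export(name = ".rpg_vec")]]
NumericVector rpg_vec(NumericVector z) {
  int n = z.size();
  NumericVector out(n);
  GetRNGstate();
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i]);
  PutRNGstate();
  return out;
}
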