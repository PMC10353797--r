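// Exact Polya-Gamma PG(1, z) sampling by the alternating-series rejection
// scheme of Devroye (as used for Bayesian logistic data augmentation).
// Uses R's RNG throughout so draws are reproducible under set.seed().

#include <Rcpp.h>
#include "polya_gamma.h"

using namespace Rcpp;

static const double TRUNC = 0.64;  // series/inverse-Gaussian switch point

// n-th coefficient of the alternating series for the J*(1, z) density
static double a_coef(int n, double x) {
  double k = n + 0.5;
  if (x > TRUNC) {
    return M_PI * k * std::exp(-0.5 * k * k * M_PI * M_PI * x);
  }
  return std::pow(2.0 / (M_PI * x), 1.5) * M_PI * k *
         std::exp(-2.0 * k * k / x);
}

// P(X <= TRUNC) weight of the left (inverse-Gaussian) mixture component,
// computed in log space for stability
static double mass_texpon(double z) {
  double t = TRUNC;
  double fz = 0.125 * M_PI * M_PI + 0.5 * z * z;
  double b = std::sqrt(1.0 / t) * (t * z - 1.0);
  double a = -std::sqrt(1.0 / t) * (t * z + 1.0);
  double x0 = std::log(fz) + fz * t;
  double xb = x0 - z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + z + R::pnorm(a, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, TRUNC];
// z = 0 (mu = Inf) falls through to the first branch with acceptance 1
static double rtigauss(double z) {
  double t = TRUNC;
  double X = t + 1.0;
  if (1.0 / z > t) {
    double alpha = 0.0;
    while (R::unif_rand() > alpha) {
      double E1 = R::exp_rand();
      double E2 = R::exp_rand();
      while (E1 * E1 > 2.0 * E2 / t) {
        E1 = R::exp_rand();
        E2 = R::exp_rand();
      }
      X = t / ((1.0 + t * E1) * (1.0 + t * E1));
      alpha = std::exp(-0.5 * z * z * X);
    }
  } else {
    double mu = 1.0 / z;
    while (X > t) {
      double Y = R::norm_rand();
      Y *= Y;
      double mu_Y = mu * Y;
      X = mu + 0.5 * mu * mu_Y -
          0.5 * mu * std::sqrt(4.0 * mu_Y + mu_Y * mu_Y);
      if (R::unif_rand() > mu / (mu + X)) X = mu * mu / X;
    }
  }
  return X;
}

// one exact PG(1, z) draw
double rpg1(double z) {
  z = std::fabs(z) * 0.5;
  double fz = 0.125 * M_PI * M_PI + 0.5 * z * z;
  for (;;) {
    double X;
    if (R::unif_rand() < mass_texpon(z)) {
      X = TRUNC + R::exp_rand() / fz;
    } else {
      X = rtigauss(z);
    }
    // squeeze acceptance via the alternating series
    double S = a_coef(0, X);
    double Y = R::unif_rand() * S;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        S -= a_coef(n, X);
        if (Y <= S) return 0.25 * X;
      } else {
        S += a_coef(n, X);
        if (Y > S) break;
      }
    }
  }
}

//' Polya-Gamma random draws
//'
//' Exact draws from the PG(1, z) distribution, the augmentation variable of
//' logistic likelihoods: if omega ~ PG(1, z) then
//' E(omega) = tanh(z/2) / (2 z) (1/4 at z = 0).
//'
//' @param n number of draws.
//' @param z numeric vector of tilting parameters (recycled to length `n`).
//' @return Numeric vector of `n` positive draws.
//' @export
// [[Rcpp::export]]
NumericVector rpg(int n, NumericVector z) {
  if (n < 0) stop("n must be non-negative");
  NumericVector out(n);
  int m = z.size();
  if (m == 0) stop("z must be non-empty");
  for (int i = 0; i < n; ++i) {
    double zi = z[i % m];
    if (!R_finite(zi)) stop("z must be finite");
    out[i] = rpg1(zi);
  }
  return out;
}
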