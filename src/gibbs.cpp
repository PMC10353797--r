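// Category-wise Gibbs sampler for the geo-additive multinomial logit model
// with Polya-Gamma augmentation.
//
// Holding the other non-reference category's predictor fixed, the
// conditional likelihood of category r is binary-logistic with offset
// C_i = log(sum of exp(eta_s) over the other categories, reference
// included), so PG augmentation yields exact Gaussian full conditionals
// for every coefficient block:
//   linear beta      : diffuse prior (precision 0)
//   spline theta     : prior precision K / sigma2_e     (RW2 penalty)
//   structured g     : prior precision Qs / delta       (intrinsic GMRF)
//   unstructured h   : prior precision I / tau2
// Variances get conjugate inverse-gamma updates; the smooth and spatial
// blocks are re-centred each iteration with the mean absorbed into the
// per-category intercept (sum-to-zero identification).
//
// All randomness comes from R's RNG (set.seed() reproducibility).

#include <RcppArmadillo.h>
#include "polya_gamma.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// log(1 + exp(x)) without overflow
static inline double log1p_exp(double x) {
  if (x > 35.0) return x + std::exp(-x);
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// draw from N(P^{-1} b, P^{-1}) given precision P (modified in place check)
static arma::vec draw_gaussian(const arma::mat& P, const arma::vec& b) {
  arma::mat L;
  if (!arma::chol(L, P, "lower")) {
    stop("non-positive-definite conditional precision in a block update");
  }
  arma::vec m = arma::solve(arma::trimatu(L.t()),
                            arma::solve(arma::trimatl(L), b));
  arma::vec z(b.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) z[i] = R::norm_rand();
  return m + arma::solve(arma::trimatu(L.t()), z);
}

static double rinvgamma(double shape, double rate) {
  // R::rgamma takes (shape, scale)
  double g = R::rgamma(shape, 1.0 / rate);
  if (g <= 0.0) g = std::numeric_limits<double>::min();
  return 1.0 / g;
}

// [[Rcpp::export]]
List gibbs_pg_cpp(const arma::ivec& y,        // 0 = reference, 1, 2
                  const arma::mat& X,         // n x p linear design
                  const arma::mat& B,         // n x J spline basis (J=0: off)
                  const arma::mat& Kpen,      // J x J RW2 penalty
                  const arma::ivec& region,   // 1-based region index (0-size: off)
                  const arma::mat& Qs,        // R x R unscaled ICAR matrix
                  const bool has_spline,
                  const bool has_struct,
                  const bool has_unstruct,
                  const int n_regions,
                  const int rank_Qs,
                  const int n_iter,
                  const int burn_in,
                  const int thin,
                  const double prior_shape,
                  const double prior_rate,
                  const double init_var,
                  const arma::ivec& cat_order) {  // permutation of {1,2}
  const int n = X.n_rows;
  const int p = X.n_cols;
  const int J = has_spline ? B.n_cols : 0;
  const int R_ = (has_struct || has_unstruct) ? n_regions : 0;
  const int n_keep = (n_iter - burn_in) / thin;
  if (n_keep < 1) stop("no retained draws: check n_iter/burn_in/thin");

  // state, one column per non-reference category
  arma::mat beta(p, 2, arma::fill::zeros);
  arma::mat theta(std::max(J, 1), 2, arma::fill::zeros);
  arma::mat g(std::max(R_, 1), 2, arma::fill::zeros);
  arma::mat h(std::max(R_, 1), 2, arma::fill::zeros);
  arma::vec sigma2_e(2), delta(2), tau2(2);
  sigma2_e.fill(init_var);
  delta.fill(init_var);
  tau2.fill(init_var);

  // storage
  arma::cube beta_draws(n_keep, p, 2);
  arma::cube theta_draws(has_spline ? n_keep : 0, J, 2);
  arma::cube g_draws(has_struct ? n_keep : 0, R_, 2);
  arma::cube h_draws(has_unstruct ? n_keep : 0, R_, 2);
  arma::mat sigma2_draws(has_spline ? n_keep : 0, 2);
  arma::mat delta_draws(has_struct ? n_keep : 0, 2);
  arma::mat tau2_draws(has_unstruct ? n_keep : 0, 2);
  arma::vec dev_draws(n_keep);

  arma::uvec reg0;  // 0-based region index
  if (R_ > 0) {
    reg0.set_size(n);
    for (int i = 0; i < n; ++i) reg0[i] = region[i] - 1;
  }

  // eta columns maintained incrementally
  arma::mat eta(n, 2, arma::fill::zeros);
  auto recompute_eta = [&](int r) {
    arma::vec e = X * beta.col(r);
    if (has_spline) e += B * theta.col(r);
    if (has_struct) {
      for (int i = 0; i < n; ++i) e[i] += g(reg0[i], r);
    }
    if (has_unstruct) {
      for (int i = 0; i < n; ++i) e[i] += h(reg0[i], r);
    }
    eta.col(r) = e;
  };
  recompute_eta(0);
  recompute_eta(1);

  arma::vec omega(n), zwork(n), kappa(n), C(n), partial(n);

  int keep = 0;
  for (int iter = 0; iter < n_iter; ++iter) {
    for (int oi = 0; oi < 2; ++oi) {
      const int r = cat_order[oi] - 1;
      const int other = 1 - r;
      // offset from the competing category (reference contributes exp(0))
      for (int i = 0; i < n; ++i) C[i] = log1p_exp(eta(i, other));
      // PG augmentation given the current eta of this category
      for (int i = 0; i < n; ++i) {
        double psi = eta(i, r) - C[i];
        if (!std::isfinite(psi)) stop("non-finite predictor in augmentation");
        omega[i] = rpg1(psi);
        kappa[i] = ((y[i] == r + 1) ? 1.0 : 0.0) - 0.5;
        zwork[i] = kappa[i] / omega[i] + C[i];
      }

      // --- linear block (diffuse prior) ---
      partial = eta.col(r) - X * beta.col(r);
      {
        arma::mat Xw = X;
        Xw.each_col() %= omega;
        arma::mat P = X.t() * Xw;
        arma::vec b = X.t() * (omega % (zwork - partial));
        beta.col(r) = draw_gaussian(P, b);
      }
      eta.col(r) = partial + X * beta.col(r);

      // --- spline block ---
      if (has_spline) {
        partial = eta.col(r) - B * theta.col(r);
        arma::mat Bw = B;
        Bw.each_col() %= omega;
        arma::mat P = B.t() * Bw + Kpen / sigma2_e[r];
        arma::vec b = B.t() * (omega % (zwork - partial));
        arma::vec th = draw_gaussian(P, b);
        arma::vec fit = B * th;
        eta.col(r) = partial + fit;
        // centre: basis rows sum to 1, so shifting all coefficients by -c
        // subtracts c from the fitted curve; absorb c into the intercept
        double c = arma::mean(fit);
        th -= c;
        beta(0, r) += c;
        theta.col(r) = th;
      }

      // --- structured spatial block (intrinsic GMRF prior) ---
      if (has_struct) {
        arma::vec gr = g.col(r);
        for (int i = 0; i < n; ++i) partial[i] = eta(i, r) - gr[reg0[i]];
        arma::vec sw(R_, arma::fill::zeros), b(R_, arma::fill::zeros);
        for (int i = 0; i < n; ++i) {
          sw[reg0[i]] += omega[i];
          b[reg0[i]] += omega[i] * (zwork[i] - partial[i]);
        }
        arma::mat P = Qs / delta[r];
        P.diag() += sw;
        arma::vec gnew = draw_gaussian(P, b);
        for (int i = 0; i < n; ++i) eta(i, r) = partial[i] + gnew[reg0[i]];
        double c = arma::mean(gnew);
        gnew -= c;
        beta(0, r) += c;
        g.col(r) = gnew;
      }

      // --- unstructured spatial block (iid Gaussian prior) ---
      if (has_unstruct) {
        arma::vec hr = h.col(r);
        for (int i = 0; i < n; ++i) partial[i] = eta(i, r) - hr[reg0[i]];
        arma::vec sw(R_, arma::fill::zeros), b(R_, arma::fill::zeros);
        for (int i = 0; i < n; ++i) {
          sw[reg0[i]] += omega[i];
          b[reg0[i]] += omega[i] * (zwork[i] - partial[i]);
        }
        arma::vec hnew(R_);
        for (int k = 0; k < R_; ++k) {
          double prec = sw[k] + 1.0 / tau2[r];
          double m = b[k] / prec;
          hnew[k] = m + R::norm_rand() / std::sqrt(prec);
        }
        for (int i = 0; i < n; ++i) eta(i, r) = partial[i] + hnew[reg0[i]];
        double c = arma::mean(hnew);
        hnew -= c;
        beta(0, r) += c;
        h.col(r) = hnew;
      }

      // --- conjugate variance updates ---
      if (has_spline) {
        double ss = arma::as_scalar(theta.col(r).t() * Kpen * theta.col(r));
        sigma2_e[r] = rinvgamma(prior_shape + 0.5 * (J - 2),
                                prior_rate + 0.5 * ss);
      }
      if (has_struct) {
        double ss = arma::as_scalar(g.col(r).t() * Qs * g.col(r));
        delta[r] = rinvgamma(prior_shape + 0.5 * rank_Qs,
                             prior_rate + 0.5 * ss);
      }
      if (has_unstruct) {
        double ss = arma::dot(h.col(r), h.col(r));
        tau2[r] = rinvgamma(prior_shape + 0.5 * R_, prior_rate + 0.5 * ss);
      }
    }

    if (iter >= burn_in && (iter - burn_in) % thin == 0 && keep < n_keep) {
      for (int r2 = 0; r2 < 2; ++r2) {
        for (int j = 0; j < p; ++j) beta_draws(keep, j, r2) = beta(j, r2);
        if (has_spline) {
          for (int j = 0; j < J; ++j) theta_draws(keep, j, r2) = theta(j, r2);
          sigma2_draws(keep, r2) = sigma2_e[r2];
        }
        if (has_struct) {
          for (int k = 0; k < R_; ++k) g_draws(keep, k, r2) = g(k, r2);
          delta_draws(keep, r2) = delta[r2];
        }
        if (has_unstruct) {
          for (int k = 0; k < R_; ++k) h_draws(keep, k, r2) = h(k, r2);
          tau2_draws(keep, r2) = tau2[r2];
        }
      }
      // multinomial deviance at the current state
      double dev = 0.0;
      for (int i = 0; i < n; ++i) {
        double m = std::max(0.0, std::max(eta(i, 0), eta(i, 1)));
        double denom = std::exp(-m) + std::exp(eta(i, 0) - m) +
                       std::exp(eta(i, 1) - m);
        double lp;
        if (y[i] == 0) {
          lp = -m - std::log(denom);
        } else {
          lp = eta(i, y[i] - 1) - m - std::log(denom);
        }
        dev += lp;
      }
      dev_draws[keep] = -2.0 * dev;
      ++keep;
    }
    if (iter % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["beta"] = beta_draws, _["theta"] = theta_draws,
      _["g"] = g_draws, _["h"] = h_draws,
      _["sigma2_e"] = sigma2_draws, _["delta"] = delta_draws,
      _["tau2"] = tau2_draws, _["deviance"] = dev_draws,
      _["n_keep"] = n_keep);
}
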