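// Gibbs sampler with data augmentation for the linear-linear piecewise
// growth model. Conjugate updates for growth-factor scores/means, factor
// covariance and residual variances; random-walk Metropolis for the knot
// on its truncated support. All randomness comes from R's RNG so chains
// are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat loading(const arma::vec& t, double gamma) {
  arma::mat L(t.n_elem, 3);
  for (arma::uword j = 0; j < t.n_elem; ++j) {
    L(j, 0) = 1.0;
    L(j, 1) = std::min(t(j), gamma);
    L(j, 2) = std::max(t(j) - gamma, 0.0);
  }
  return L;
}

// W ~ Wishart(scale S, df) via the Bartlett decomposition
static arma::mat rwishart(const arma::mat& S, double df) {
  const arma::uword p = S.n_rows;
  arma::mat C = arma::chol(S, "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (arma::uword i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - (double)i));
    for (arma::uword j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat L = C * A;
  return L * L.t();
}

// Omega ~ InverseWishart(scale S, df): Omega^{-1} ~ Wishart(S^{-1}, df)
// [[Rcpp::export]]
arma::mat cpp_draw_iwish(const arma::mat& S, double df) {
  arma::mat W = rwishart(arma::inv_sympd(arma::symmatu(S)), df);
  return arma::inv_sympd(arma::symmatu(W));
}

// Full conditional of the growth-factor means given factor scores
// [[Rcpp::export]]
arma::vec cpp_update_alpha(const arma::mat& eta, const arma::mat& omega,
                           double mu_alpha, double sigma2_alpha) {
  const arma::uword n = eta.n_rows;
  arma::mat OmInv = arma::inv_sympd(arma::symmatu(omega));
  arma::mat prec = (double)n * OmInv +
    arma::eye(3, 3) / sigma2_alpha;
  arma::mat V = arma::inv_sympd(arma::symmatu(prec));
  arma::vec rhs = arma::vec(3, arma::fill::ones) * (mu_alpha / sigma2_alpha);
  if (n > 0) rhs += OmInv * arma::sum(eta, 0).t();
  arma::vec m = V * rhs;
  arma::vec z(3);
  for (int k = 0; k < 3; ++k) z(k) = R::norm_rand();
  return m + arma::chol(V, "lower") * z;
}

// Full conditional of the factor covariance given scores and means
// [[Rcpp::export]]
arma::mat cpp_update_omega(const arma::mat& eta, const arma::vec& alpha,
                           const arma::mat& Psi, double nu) {
  arma::mat S = Psi;
  if (eta.n_rows > 0) {
    arma::mat D = eta.each_row() - alpha.t();
    S += D.t() * D;
  }
  return cpp_draw_iwish(S, nu + (double)eta.n_rows);
}

// Full conditionals of the occasion residual variances given residuals
// [[Rcpp::export]]
arma::vec cpp_update_sigma2(const arma::mat& resid, double a, double b) {
  const arma::uword J = resid.n_cols;
  const double n = (double)resid.n_rows;
  arma::vec out(J);
  for (arma::uword j = 0; j < J; ++j) {
    double rss = arma::dot(resid.col(j), resid.col(j));
    // inverse gamma via reciprocal gamma draw (R::rgamma is shape/scale);
    // the tiny-shape prior draw (n = 0 path) can underflow to 0
    double g = R::rgamma(a + n / 2.0, 1.0 / (b + rss / 2.0));
    if (g < 1e-300) g = 1e-300;
    out(j) = 1.0 / g;
  }
  return out;
}

// Full conditional of the factor scores given complete data
// [[Rcpp::export]]
arma::mat cpp_update_eta(const arma::mat& Y, const arma::mat& L,
                         const arma::mat& omega, const arma::vec& alpha,
                         const arma::vec& sigma2) {
  const arma::uword n = Y.n_rows;
  arma::mat OmInv = arma::inv_sympd(arma::symmatu(omega));
  arma::mat Lt_Dinv = L.t() * arma::diagmat(1.0 / sigma2);
  arma::mat prec = OmInv + Lt_Dinv * L;
  arma::mat V = arma::inv_sympd(arma::symmatu(prec));
  arma::mat rhs = Lt_Dinv * Y.t();              // 3 x n
  rhs.each_col() += OmInv * alpha;
  arma::mat mean = V * rhs;                     // 3 x n
  arma::mat Z(3, n);
  for (arma::uword k = 0; k < Z.n_elem; ++k) Z(k) = R::norm_rand();
  return (mean + arma::chol(V, "lower") * Z).t();
}

static double knot_log_prior(double g, int family, double lower,
                             double upper, double mu, double s2) {
  if (g <= lower || g >= upper) return R_NegInf;
  if (family == 0) return 0.0;                  // uniform, constant inside
  return -0.5 * (g - mu) * (g - mu) / s2;       // truncation mass cancels
}

// draw from the knot prior (inverse-CDF for the truncated normal)
static double knot_prior_draw(int family, double lower, double upper,
                              double mu, double s2) {
  if (family == 0) return lower + R::unif_rand() * (upper - lower);
  double s = std::sqrt(s2);
  double plo = R::pnorm(lower, mu, s, 1, 0);
  double phi = R::pnorm(upper, mu, s, 1, 0);
  double u = plo + R::unif_rand() * (phi - plo);
  double g = R::qnorm(u, mu, s, 1, 0);
  if (g <= lower) g = std::nextafter(lower, upper);
  if (g >= upper) g = std::nextafter(upper, lower);
  return g;
}

// [[Rcpp::export]]
List cpp_gibbs_chain(const arma::mat& Y0, const arma::imat& obs,
                     const arma::vec& tcodes, const arma::vec& alpha0,
                     const arma::mat& omega0, const arma::vec& sigma20,
                     double gamma0, int knot_family, double knot_lower,
                     double knot_upper, double knot_mu, double knot_s2,
                     double mu_alpha, double sigma2_alpha,
                     const arma::mat& Psi, double nu, double a, double b,
                     int n_iter, int burn_in, int thin, double prop_sd,
                     bool adapt) {
  const arma::uword n = Y0.n_rows;
  const arma::uword J = tcodes.n_elem;
  const int total = burn_in + n_iter;
  const int n_keep = n_iter / thin;
  const arma::uword p = 3 + 6 + J + 1;

  arma::mat Y = Y0;
  arma::vec alpha = alpha0;
  arma::mat omega = omega0;
  arma::vec sigma2 = sigma20;
  double gamma = gamma0;
  arma::mat eta(n, 3);
  if (n > 0) eta = arma::repmat(alpha.t(), n, 1);

  // missing cells start at the model-implied mean under the inits
  arma::mat L = loading(tcodes, gamma);
  for (arma::uword i = 0; i < n; ++i)
    for (arma::uword j = 0; j < J; ++j)
      if (!obs(i, j)) Y(i, j) = arma::dot(L.row(j), alpha);

  arma::mat draws(n_keep, p);
  int kept = 0, acc_post = 0, n_post = 0, acc_win = 0, win = 0;
  double lp_cur = knot_log_prior(gamma, knot_family, knot_lower, knot_upper,
                                 knot_mu, knot_s2);

  for (int s = 1; s <= total; ++s) {
    L = loading(tcodes, gamma);

    if (n > 0) {
      // (1) data augmentation: missing y_ij ~ N(L_j' eta_i, sigma2_j)
      for (arma::uword i = 0; i < n; ++i)
        for (arma::uword j = 0; j < J; ++j)
          if (!obs(i, j))
            Y(i, j) = arma::dot(L.row(j), eta.row(i).t()) +
              std::sqrt(sigma2(j)) * R::norm_rand();

      // (2) factor scores
      eta = cpp_update_eta(Y, L, omega, alpha, sigma2);
    }

    // (3) growth-factor means
    alpha = cpp_update_alpha(eta, omega, mu_alpha, sigma2_alpha);

    // (4) factor covariance
    omega = cpp_update_omega(eta, alpha, Psi, nu);

    // (5) residual variances
    arma::mat resid(n, J);
    if (n > 0) {
      resid = Y - eta * L.t();
      sigma2 = cpp_update_sigma2(resid, a, b);
    } else {
      sigma2 = cpp_update_sigma2(arma::mat(0, J), a, b);
    }

    // (6) knot: Metropolis on the complete-data likelihood. The kernel
    // mixes a Gaussian random walk with occasional independence proposals
    // from the prior, which lets chains jump between well-separated knot
    // modes (the prior and proposal densities cancel, so the acceptance
    // ratio of an independence move is the bare likelihood ratio).
    bool indep = R::unif_rand() < 0.10;
    double prop, lp_prop;
    if (indep) {
      prop = knot_prior_draw(knot_family, knot_lower, knot_upper, knot_mu,
                             knot_s2);
      lp_prop = knot_log_prior(prop, knot_family, knot_lower, knot_upper,
                               knot_mu, knot_s2);
    } else {
      prop = gamma + prop_sd * R::norm_rand();
      lp_prop = knot_log_prior(prop, knot_family, knot_lower, knot_upper,
                               knot_mu, knot_s2);
    }
    bool accepted = false;
    if (R_finite(lp_prop)) {
      double dll = 0.0;
      if (n > 0) {
        arma::mat Lp = loading(tcodes, prop);
        arma::mat rp = Y - eta * Lp.t();
        for (arma::uword j = 0; j < J; ++j) {
          double d = arma::dot(rp.col(j), rp.col(j)) -
            arma::dot(resid.col(j), resid.col(j));
          dll -= 0.5 * d / sigma2(j);
        }
      }
      double lratio = indep ? dll : dll + lp_prop - lp_cur;
      if (std::isnan(lratio))
        stop("non-finite likelihood in knot update at iteration %d", s);
      if (std::log(R::unif_rand()) < lratio) {
        gamma = prop;
        lp_cur = lp_prop;
        accepted = true;
      }
    }
    if (s > burn_in) {
      n_post++;
      if (accepted) acc_post++;
    } else if (adapt && !indep) {
      win++;
      if (accepted) acc_win++;
      if (win == 100) {              // adapt toward 25-45% acceptance
        double rate = acc_win / 100.0;
        if (rate < 0.25) prop_sd *= 0.8;
        else if (rate > 0.45) prop_sd *= 1.25;
        win = 0;
        acc_win = 0;
      }
    }

    if (!alpha.is_finite() || !sigma2.is_finite() || !omega.is_finite())
      stop("non-finite parameter state at iteration %d", s);

    if (s > burn_in && (s - burn_in) % thin == 0 && kept < n_keep) {
      arma::uword c = 0;
      for (int k = 0; k < 3; ++k) draws(kept, c++) = alpha(k);
      draws(kept, c++) = omega(0, 0);
      draws(kept, c++) = omega(1, 0);
      draws(kept, c++) = omega(2, 0);
      draws(kept, c++) = omega(1, 1);
      draws(kept, c++) = omega(2, 1);
      draws(kept, c++) = omega(2, 2);
      for (arma::uword j = 0; j < J; ++j) draws(kept, c++) = sigma2(j);
      draws(kept, c++) = gamma;
      kept++;
    }
  }

  return List::create(_["draws"] = draws,
                      _["acceptance"] = n_post > 0 ?
                        (double)acc_post / n_post : NA_REAL,
                      _["prop_sd"] = prop_sd);
}
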