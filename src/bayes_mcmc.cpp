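// Single-site Gibbs samplers for Bayesian marker-effect models
// (BayesB, BayesCpi, BayesN, BayesS, BayesR).
//
// Model: y = X beta + sum_j Z_j alpha_j + e, with family-specific priors
// on alpha. Residuals are maintained incrementally; the R-level RNG is
// used throughout so results are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double rinvchi2(double df, double scale) {
  // scaled inverse chi-square: df * scale / chi2_df
  return df * scale / R::rchisq(df);
}

// Sample one marker under a spike-and-normal prior with variance v_j.
// rhs = Z_j' (r + Z_j * alpha_old). Returns new alpha (0 if excluded)
// and updates r in place. log_odds_pi = log(pi / (1 - pi)).
static inline double update_marker(const arma::vec& Zj, double zz,
                                   arma::vec& r, double alpha_old,
                                   double vj, double se2,
                                   double log_odds_pi, int& delta) {
  double rhs = arma::dot(Zj, r) + zz * alpha_old;
  double alpha_new = 0.0;
  if (vj <= 0.0) {
    delta = 0;
  } else {
    double vz = zz * vj + se2;
    double logBF = 0.5 * std::log(se2 / vz) + 0.5 * rhs * rhs * vj / (se2 * vz);
    double lodds = log_odds_pi + logBF;
    double p1 = 1.0 / (1.0 + std::exp(-lodds));
    delta = (R::runif(0.0, 1.0) < p1) ? 1 : 0;
    if (delta == 1) {
      double cj = zz + se2 / vj;
      alpha_new = R::rnorm(rhs / cj, std::sqrt(se2 / cj));
    }
  }
  if (alpha_new != alpha_old) {
    r += Zj * (alpha_old - alpha_new);
  }
  return alpha_new;
}

// [[Rcpp::export(name = ".bayes_mcmc_cpp")]]
List bayes_mcmc_cpp(const arma::mat& Z,        // n x m centred genotypes
                    const arma::mat& X,        // n x p fixed-effect design
                    const arma::vec& y,
                    const std::string family,  // "B","Cpi","N","S","R"
                    const int niter, const int burnin, const int thin,
                    const double pi_fixed,     // <0 => estimate (uniform prior)
                    const arma::vec gamma,     // BayesR variance classes
                    const arma::ivec window_id,// BayesN window per marker (1-based)
                    const arma::vec wS,        // 2p(1-p) per marker (BayesS)
                    const double s_prior_sd,
                    const double s_proposal_sd,
                    const double df_t) {       // BayesB t degrees of freedom
  const int n = Z.n_rows, m = Z.n_cols, p = X.n_cols;
  arma::vec zz(m), xx(p);
  for (int j = 0; j < m; ++j) zz(j) = arma::dot(Z.col(j), Z.col(j));
  for (int l = 0; l < p; ++l) xx(l) = arma::dot(X.col(l), X.col(l));

  // state
  arma::vec beta(p, arma::fill::zeros);
  arma::vec alpha(m, arma::fill::zeros);
  arma::ivec delta(m, arma::fill::zeros);
  arma::ivec comp(m, arma::fill::zeros);       // BayesR component (0..3)
  arma::vec sigma2_j(m, arma::fill::zeros);    // BayesB per-marker variances
  double pi = (pi_fixed >= 0.0) ? pi_fixed : 0.5;
  double pi_w = 0.5;                           // BayesN window inclusion prob
  double S = 0.0;                              // BayesS exponent
  arma::vec pi_r = {0.5, 0.25, 0.15, 0.10};    // BayesR weights

  const double vary = arma::var(y);
  double se2 = 0.5 * vary;
  double msx = arma::accu(zz) / n;             // ~ 2 sum p(1-p)
  if (msx <= 0) msx = 1.0;
  double pi0 = (pi_fixed >= 0.0 && pi_fixed > 0.0) ? pi_fixed : 0.5;
  double sigma2 = 0.5 * vary / (msx * pi0);    // common effect variance
  const double nu0 = 4.0, nu_e = 4.0;
  double S0 = sigma2 * (nu0 - 2.0) / nu0;             // prior scale, effects
  const double Se = 0.5 * vary * (nu_e - 2.0) / nu_e; // prior scale, residual
  double scale_t = S0;                          // BayesB t scale^2
  // weak gamma hyperprior on the scale, centred on its initial value
  const double hyper_shape = 1.0;
  const double hyper_rate = 1.0 / S0;
  if (family == "B") {
    for (int j = 0; j < m; ++j) sigma2_j(j) = rinvchi2(df_t, scale_t);
  }

  // BayesN window bookkeeping
  int n_win = 0;
  std::vector< std::vector<int> > win_members;
  arma::ivec W;
  if (family == "N") {
    n_win = window_id.max();
    win_members.assign(n_win, std::vector<int>());
    for (int j = 0; j < m; ++j) win_members[window_id(j) - 1].push_back(j);
    W = arma::ivec(n_win, arma::fill::ones);
  }

  arma::vec r = y - X * beta;                  // residual (alpha = 0)

  const int n_keep = (niter - burnin) / thin;
  arma::vec effect_sum(m, arma::fill::zeros);
  arma::vec incl_sum(m, arma::fill::zeros);
  arma::vec beta_sum(p, arma::fill::zeros);
  arma::vec pi_chain(n_keep), S_chain(n_keep);
  arma::vec sa2_chain(n_keep), se2_chain(n_keep);
  arma::mat weight_chain(n_keep, 4, arma::fill::zeros);
  int kept = 0;

  const arma::vec gam = gamma;

  for (int it = 1; it <= niter; ++it) {
    // ---- fixed effects, flat prior
    for (int l = 0; l < p; ++l) {
      double rhs = arma::dot(X.col(l), r) + xx(l) * beta(l);
      double bnew = R::rnorm(rhs / xx(l), std::sqrt(se2 / xx(l)));
      r += X.col(l) * (beta(l) - bnew);
      beta(l) = bnew;
    }

    double log_odds = std::log(pi) - std::log1p(-pi);
    if (pi <= 0.0) log_odds = -700.0;
    if (pi >= 1.0) log_odds = 700.0;

    // ---- marker effects
    if (family == "Cpi" || family == "B" || family == "S") {
      for (int j = 0; j < m; ++j) {
        double vj;
        if (family == "B") vj = sigma2_j(j);
        else if (family == "S") vj = std::pow(wS(j), S) * sigma2;
        else vj = sigma2;
        int dj = 0;
        alpha(j) = update_marker(Z.col(j), zz(j), r, alpha(j), vj, se2,
                                 log_odds, dj);
        delta(j) = dj;
      }
    } else if (family == "R") {
      for (int j = 0; j < m; ++j) {
        double rhs = arma::dot(Z.col(j), r) + zz(j) * alpha(j);
        // component log-probabilities with the effect integrated out
        arma::vec lp(4);
        for (int k = 0; k < 4; ++k) {
          double vk = gam(k) * sigma2;
          if (vk <= 0.0) {
            lp(k) = std::log(std::max(pi_r(k), 1e-300));
          } else {
            double vz = zz(j) * vk + se2;
            lp(k) = std::log(std::max(pi_r(k), 1e-300)) +
              0.5 * std::log(se2 / vz) + 0.5 * rhs * rhs * vk / (se2 * vz);
          }
        }
        lp -= lp.max();                        // log-space renormalization
        arma::vec pr = arma::exp(lp);
        pr /= arma::accu(pr);
        double u = R::runif(0.0, 1.0), acc = 0.0;
        int k_new = 3;
        for (int k = 0; k < 4; ++k) { acc += pr(k); if (u <= acc) { k_new = k; break; } }
        comp(j) = k_new;
        double alpha_new = 0.0;
        if (k_new > 0) {
          double vk = gam(k_new) * sigma2;
          double cj = zz(j) + se2 / vk;
          alpha_new = R::rnorm(rhs / cj, std::sqrt(se2 / cj));
        }
        if (alpha_new != alpha(j)) r += Z.col(j) * (alpha(j) - alpha_new);
        alpha(j) = alpha_new;
        delta(j) = (k_new > 0) ? 1 : 0;
      }
    } else if (family == "N") {
      double log_odds_w = std::log(pi_w) - std::log1p(-pi_w);
      for (int w = 0; w < n_win; ++w) {
        const std::vector<int>& mem = win_members[w];
        if (mem.empty()) continue;
        // window contribution with current inner state
        arma::vec u(n, arma::fill::zeros);
        for (size_t t = 0; t < mem.size(); ++t) {
          int j = mem[t];
          if (delta(j) == 1 && alpha(j) != 0.0) u += Z.col(j) * alpha(j);
        }
        arma::vec r0 = (W(w) == 1) ? arma::vec(r + u) : r;
        double lodds = log_odds_w +
          (2.0 * arma::dot(u, r0) - arma::dot(u, u)) / (2.0 * se2);
        double p1 = 1.0 / (1.0 + std::exp(-lodds));
        int w_new = (R::runif(0.0, 1.0) < p1) ? 1 : 0;
        if (w_new == 1) {
          r = r0 - u;
          W(w) = 1;
          for (size_t t = 0; t < mem.size(); ++t) {
            int j = mem[t];
            int dj = 0;
            alpha(j) = update_marker(Z.col(j), zz(j), r, alpha(j), sigma2,
                                     se2, log_odds, dj);
            delta(j) = dj;
          }
        } else {
          r = r0;
          W(w) = 0;
          // refresh the gated inner state from its prior
          for (size_t t = 0; t < mem.size(); ++t) {
            int j = mem[t];
            delta(j) = (R::runif(0.0, 1.0) < pi) ? 1 : 0;
            alpha(j) = (delta(j) == 1) ? R::rnorm(0.0, std::sqrt(sigma2)) : 0.0;
          }
        }
      }
    }

    // ---- family hyperparameters
    int k_in = 0;
    double ssq = 0.0;                           // sum alpha^2 / relative-variance
    for (int j = 0; j < m; ++j) {
      if (delta(j) == 1) {
        ++k_in;
        if (family == "S") ssq += alpha(j) * alpha(j) / std::pow(wS(j), S);
        else if (family == "R") ssq += alpha(j) * alpha(j) / gam(comp(j));
        else ssq += alpha(j) * alpha(j);
      }
    }
    if (family == "B") {
      double inv_sum = 0.0;
      for (int j = 0; j < m; ++j) {
        if (delta(j) == 1) {
          sigma2_j(j) = rinvchi2(df_t + 1.0,
                                 (df_t * scale_t + alpha(j) * alpha(j)) / (df_t + 1.0));
        } else {
          sigma2_j(j) = rinvchi2(df_t, scale_t);
        }
        inv_sum += 1.0 / sigma2_j(j);
      }
      // conjugate gamma update of the common t scale
      scale_t = R::rgamma(0.5 * m * df_t + hyper_shape,
                          1.0 / (0.5 * df_t * inv_sum + hyper_rate));
    } else {
      // common effect variance with a hierarchical gamma prior on its
      // scale: under an uninformative likelihood both collapse, giving
      // genuine shrinkage on pure-noise phenotypes
      sigma2 = rinvchi2(nu0 + k_in, (ssq + nu0 * S0) / (nu0 + k_in));
      S0 = R::rgamma(0.5 * nu0 + hyper_shape,
                     1.0 / (0.5 * nu0 / sigma2 + hyper_rate));
    }

    if (family == "S") {
      // random-walk Metropolis on the MAF-coupling exponent S
      double S_new = S + R::rnorm(0.0, 1.0) * s_proposal_sd;
      double ll_old = 0.0, ll_new = 0.0;
      for (int j = 0; j < m; ++j) {
        if (delta(j) == 1) {
          double lw = std::log(wS(j));
          ll_old += -0.5 * (S * lw + alpha(j) * alpha(j) /
                            (std::pow(wS(j), S) * sigma2));
          ll_new += -0.5 * (S_new * lw + alpha(j) * alpha(j) /
                            (std::pow(wS(j), S_new) * sigma2));
        }
      }
      double lprior = -0.5 * (S_new * S_new - S * S) / (s_prior_sd * s_prior_sd);
      if (std::log(R::runif(0.0, 1.0)) < ll_new - ll_old + lprior) S = S_new;
    }

    // ---- inclusion probabilities
    if (family == "R") {
      arma::vec cnt(4, arma::fill::zeros);
      for (int j = 0; j < m; ++j) cnt(comp(j)) += 1.0;
      double tot = 0.0;
      for (int k = 0; k < 4; ++k) {
        pi_r(k) = R::rgamma(cnt(k) + 1.0, 1.0);  // Dirichlet(1,1,1,1)
        tot += pi_r(k);
      }
      pi_r /= tot;
    } else if (pi_fixed < 0.0) {
      pi = R::rbeta(1.0 + k_in, 1.0 + (m - k_in));
      if (family == "N") {
        int w_in = 0;
        for (int w = 0; w < n_win; ++w) w_in += W(w);
        pi_w = R::rbeta(1.0 + w_in, 1.0 + (n_win - w_in));
      }
    }

    // ---- residual variance
    double sse = arma::dot(r, r);
    se2 = rinvchi2(nu_e + n, (sse + nu_e * Se) / (nu_e + n));

    // ---- save
    if (it > burnin && (it - burnin) % thin == 0 && kept < n_keep) {
      // effective inclusion: for BayesN the window gate must be open too
      for (int j = 0; j < m; ++j) {
        bool in = (delta(j) == 1) &&
          (family != "N" || W(window_id(j) - 1) == 1);
        if (in) {
          effect_sum(j) += alpha(j);
          incl_sum(j) += 1.0;
        }
      }
      beta_sum += beta;
      arma::vec gvec = y - X * beta - r;        // current genetic values
      sa2_chain(kept) = arma::var(gvec);
      se2_chain(kept) = se2;
      pi_chain(kept) = pi;
      S_chain(kept) = S;
      weight_chain.row(kept) = pi_r.t();
      ++kept;
    }
  }

  return List::create(
    _["effect_means"] = effect_sum / std::max(kept, 1),
    _["inclusion_prob"] = incl_sum / std::max(kept, 1),
    _["beta_means"] = beta_sum / std::max(kept, 1),
    _["pi_samples"] = pi_chain,
    _["S_samples"] = S_chain,
    _["component_weight_samples"] = weight_chain,
    _["sigma_a2_samples"] = sa2_chain,
    _["sigma_e2_samples"] = se2_chain,
    _["n_kept"] = kept);
}
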