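// Metropolis-within-Gibbs sampler for Leroux CAR spatial smoothing models.
//
// Incidence model:  y_i   ~ Poisson(E_i * exp(mu + S_i))
// Survival model:   d_ij  ~ Poisson(e_ij + t_ij * lambda_j * exp(S_i))
// Spatial prior:    S ~ N(0, Q^{-1}),  Q = (1/sigma2)(rho (D - W) + (1-rho) I)
// Hyperpriors:      mu, log lambda_j ~ N(0, mu_sd^2); sigma ~ HN(0, sigma_sd^2);
//                   rho ~ Uniform(0, 1)
//
// S is updated single-site (O(degree) per site via the sparse precision),
// mu / log lambda_j by random-walk Metropolis, log sigma2 and logit rho by
// random-walk Metropolis using the precomputed eigenvalues of D - W for the
// determinant term. Step sizes adapt in batches of 50 during burn-in only
// (target acceptance 0.44).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double logit(double p) { return std::log(p / (1.0 - p)); }
static inline double inv_logit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// [[Rcpp::export]]
List car_chain_cpp(int model,
                   NumericVector y, NumericVector E,
                   NumericMatrix dmat, NumericMatrix emat, NumericMatrix tmat,
                   List nbrs, IntegerMatrix edges, NumericVector eig,
                   int n_iter, int n_burn, int thin,
                   double mu, NumericVector S_init,
                   double rho, double sigma2, NumericVector loglam_init,
                   bool sample_rho, bool sample_sigma2, bool prior_only,
                   double step_S0, double step_mu0, double step_lrho0,
                   double step_lsig0, double step_llam0,
                   bool adapt, double pr_mu_sd, double pr_sigma_sd) {
  const int n = S_init.size();
  const int J = (model == 1) ? dmat.ncol() : 0;
  const int m = edges.nrow();
  const double target = 0.44;

  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = nbrs[i];
    nb[i].assign(v.begin(), v.end());
    for (size_t k = 0; k < nb[i].size(); ++k) nb[i][k] -= 1;  // 0-based
  }
  std::vector<double> deg(n);
  for (int i = 0; i < n; ++i) deg[i] = (double)nb[i].size();

  std::vector<double> S(S_init.begin(), S_init.end());
  std::vector<double> expS(n);
  for (int i = 0; i < n; ++i) expS[i] = std::exp(S[i]);
  std::vector<double> loglam(loglam_init.begin(), loglam_init.end());
  std::vector<double> lam(J);
  for (int j = 0; j < J; ++j) lam[j] = std::exp(loglam[j]);
  double lsig = std::log(sigma2);
  double lrho = (rho <= 0.0) ? -20.0 : logit(std::min(rho, 1.0 - 1e-12));

  // running sums for the incidence mu update
  double sum_y = 0.0, sumEexpS = 0.0;
  if (model == 0) {
    for (int i = 0; i < n; ++i) { sum_y += y[i]; sumEexpS += E[i] * expS[i]; }
  }

  // area-level likelihood as a function of S_i (constants in S_i dropped)
  auto ll_area = [&](int i, double Si, double expSi) -> double {
    if (prior_only) return 0.0;
    if (model == 0) return y[i] * Si - E[i] * std::exp(mu) * expSi;
    double ll = 0.0;
    for (int j = 0; j < J; ++j) {
      double mean = emat(i, j) + tmat(i, j) * lam[j] * expSi;
      if (mean <= 0.0) {
        if (dmat(i, j) > 0.0) return R_NegInf;
        continue;
      }
      ll += dmat(i, j) * std::log(mean) - mean;
    }
    return ll;
  };

  // finite-posterior check at initialization
  {
    double ll0 = 0.0;
    for (int i = 0; i < n; ++i) ll0 += ll_area(i, S[i], expS[i]);
    if (!R_finite(ll0))
      stop("non-finite log-posterior at initialization "
           "(check expected counts / person-time for zero cells)");
  }

  // retained draws
  const int n_keep = (n_iter - n_burn) / thin;
  const int n_hyper = 2 + ((model == 0) ? 1 : J);
  NumericMatrix draws(n_keep, n);
  NumericMatrix hyper(n_keep, n_hyper);

  // step sizes and acceptance bookkeeping
  std::vector<double> step_S(n, step_S0);
  double step_mu = step_mu0, step_lsig = step_lsig0, step_lrho = step_lrho0;
  std::vector<double> step_llam(J, step_llam0);
  std::vector<int> accS_batch(n, 0);
  int acc_mu_b = 0, acc_sig_b = 0, acc_rho_b = 0;
  std::vector<int> acc_llam_b(J, 0);
  long accS_post = 0, acc_mu_post = 0, acc_sig_post = 0, acc_rho_post = 0;
  long acc_llam_post = 0, nS_post = 0, n_scalar_post = 0;
  const int batch = 50;
  int batch_idx = 0;

  RNGScope scope;
  int keep_row = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    if (iter % 512 == 0) Rcpp::checkUserInterrupt();
    const bool post = iter > n_burn;
    const double inv_sig = 1.0 / std::exp(lsig);

    // --- spatial effects, single site --------------------------------------
    for (int i = 0; i < n; ++i) {
      double prec_i = (rho * deg[i] + 1.0 - rho) * inv_sig;
      double nbr_sum = 0.0;
      for (size_t k = 0; k < nb[i].size(); ++k) nbr_sum += S[nb[i][k]];
      double lin_i = rho * inv_sig * nbr_sum;  // -Q_ij sum_j S_j
      double prop = S[i] + step_S[i] * norm_rand();
      double expProp = std::exp(prop);
      double lr = ll_area(i, prop, expProp) - ll_area(i, S[i], expS[i]) -
        0.5 * prec_i * (prop * prop - S[i] * S[i]) + lin_i * (prop - S[i]);
      if (R_finite(lr) && std::log(unif_rand()) < lr) {
        if (model == 0) sumEexpS += E[i] * (expProp - expS[i]);
        S[i] = prop; expS[i] = expProp;
        accS_batch[i]++; if (post) accS_post++;
      }
      if (post) nS_post++;
    }

    // --- intercept / baselines ---------------------------------------------
    if (!prior_only) {
      if (model == 0) {
        double prop = mu + step_mu * norm_rand();
        double lr = sum_y * (prop - mu) -
          (std::exp(prop) - std::exp(mu)) * sumEexpS -
          0.5 * (prop * prop - mu * mu) / (pr_mu_sd * pr_mu_sd);
        if (R_finite(lr) && std::log(unif_rand()) < lr) {
          mu = prop; acc_mu_b++; if (post) acc_mu_post++;
        }
        if (post) n_scalar_post++;
      } else {
        for (int j = 0; j < J; ++j) {
          double prop_ll = loglam[j] + step_llam[j] * norm_rand();
          double prop_lam = std::exp(prop_ll);
          double lr = -0.5 * (prop_ll * prop_ll - loglam[j] * loglam[j]) /
            (pr_mu_sd * pr_mu_sd);
          for (int i = 0; i < n; ++i) {
            double m_old = emat(i, j) + tmat(i, j) * lam[j] * expS[i];
            double m_new = emat(i, j) + tmat(i, j) * prop_lam * expS[i];
            if (m_new <= 0.0) { if (dmat(i, j) > 0.0) { lr = R_NegInf; break; } continue; }
            double dd = dmat(i, j);
            lr += (dd > 0.0 ? dd * (std::log(m_new) - std::log(m_old)) : 0.0) -
              (m_new - m_old);
          }
          if (R_finite(lr) && std::log(unif_rand()) < lr) {
            loglam[j] = prop_ll; lam[j] = prop_lam;
            acc_llam_b[j]++; if (post) acc_llam_post++;
          }
          if (post) n_scalar_post++;
        }
      }
    }

    // quadratic forms for the hyperparameter updates
    double q1 = 0.0, q2 = 0.0;
    for (int e = 0; e < m; ++e) {
      double dS = S[edges(e, 0) - 1] - S[edges(e, 1) - 1];
      q1 += dS * dS;
    }
    for (int i = 0; i < n; ++i) q2 += S[i] * S[i];

    // --- sigma2 (log scale) ------------------------------------------------
    if (sample_sigma2) {
      double q = rho * q1 + (1.0 - rho) * q2;
      auto lp = [&](double x) {
        return -0.5 * n * x - 0.5 * q * std::exp(-x) -
          std::exp(x) / (2.0 * pr_sigma_sd * pr_sigma_sd) + 0.5 * x;
      };
      double prop = lsig + step_lsig * norm_rand();
      double lr = lp(prop) - lp(lsig);
      if (R_finite(lr) && std::log(unif_rand()) < lr) {
        lsig = prop; acc_sig_b++; if (post) acc_sig_post++;
      }
      if (post) n_scalar_post++;
    }

    // --- rho (logit scale) -------------------------------------------------
    if (sample_rho) {
      double inv_s = 1.0 / std::exp(lsig);
      auto lp = [&](double x) {
        double r = inv_logit(x);
        double ld = 0.0;
        for (int k = 0; k < n; ++k) {
          double v = r * eig[k] + (1.0 - r);
          if (v <= 0.0) return R_NegInf;
          ld += std::log(v);
        }
        return 0.5 * ld - 0.5 * inv_s * (r * q1 + (1.0 - r) * q2) +
          std::log(r) + std::log(1.0 - r);  // Uniform prior + logit Jacobian
      };
      double prop = lrho + step_lrho * norm_rand();
      double lr = lp(prop) - lp(lrho);
      if (R_finite(lr) && std::log(unif_rand()) < lr) {
        lrho = prop; acc_rho_b++; if (post) acc_rho_post++;
      }
      if (post) n_scalar_post++;
      rho = inv_logit(lrho);
    }

    // --- burn-in step-size adaptation (batches of 50) ----------------------
    if (adapt && iter <= n_burn && iter % batch == 0) {
      batch_idx++;
      double delta = std::min(0.1, 1.0 / std::sqrt((double)batch_idx));
      auto tune = [&](double step, int acc) {
        double rate = (double)acc / batch;
        return step * std::exp(rate > target ? delta : -delta);
      };
      for (int i = 0; i < n; ++i) {
        step_S[i] = tune(step_S[i], accS_batch[i]); accS_batch[i] = 0;
      }
      if (model == 0) { step_mu = tune(step_mu, acc_mu_b); acc_mu_b = 0; }
      for (int j = 0; j < J; ++j) {
        step_llam[j] = tune(step_llam[j], acc_llam_b[j]); acc_llam_b[j] = 0;
      }
      if (sample_sigma2) { step_lsig = tune(step_lsig, acc_sig_b); acc_sig_b = 0; }
      if (sample_rho) { step_lrho = tune(step_lrho, acc_rho_b); acc_rho_b = 0; }
    }

    // --- store -------------------------------------------------------------
    if (post && (iter - n_burn) % thin == 0 && keep_row < n_keep) {
      for (int i = 0; i < n; ++i)
        draws(keep_row, i) = (model == 0) ? std::exp(mu + S[i]) : expS[i];
      hyper(keep_row, 0) = rho;
      hyper(keep_row, 1) = std::exp(lsig);
      if (model == 0) hyper(keep_row, 2) = mu;
      else for (int j = 0; j < J; ++j) hyper(keep_row, 2 + j) = lam[j];
      keep_row++;
    }
  }

  double n_post_iters = (double)(n_iter - n_burn);
  NumericVector acc = NumericVector::create(
    _["S"] = nS_post > 0 ? (double)accS_post / nS_post : NA_REAL,
    _["coef"] = (model == 0)
      ? (n_post_iters > 0 && !prior_only ? acc_mu_post / n_post_iters : NA_REAL)
      : (n_post_iters > 0 && !prior_only
           ? acc_llam_post / (n_post_iters * J) : NA_REAL),
    _["sigma2"] = sample_sigma2 ? acc_sig_post / n_post_iters : NA_REAL,
    _["rho"] = sample_rho ? acc_rho_post / n_post_iters : NA_REAL);

  return List::create(_["draws"] = draws, _["hyper"] = hyper,
                      _["accept"] = acc,
                      _["step_S"] = NumericVector(step_S.begin(), step_S.end()));
}
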