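// Adaptive Metropolis-within-Gibbs sampler for the annualized
// interval-survival model: Bernoulli(S^dt) outcomes with logit-linear
// annual survival, Normal priors on fixed effects, Normal(0, sigma^2)
// plot effects and a half-Normal prior on sigma. Proposal scales adapt
// during burn-in only (diminishing adaptation, frozen afterwards so the
// retained chain satisfies detailed balance). Uses R's RNG throughout, so
// runs are reproducible under set.seed().
#include <Rcpp.h>
using namespace Rcpp;

// log survival on the annual scale from the logit-scale linear predictor
static inline double log_annual_s(double eta) {
  if (eta > 0.0) return -log1p(std::exp(-eta));
  return eta - log1p(std::exp(eta));
}

// pointwise log-likelihood of one tree x interval observation
static inline double ll_term(double eta, int alive, double dt) {
  double ls = log_annual_s(eta);
  if (alive) return dt * ls;
  double t = dt * ls;  // = log(S^dt) < 0
  double em = -expm1(t);
  if (em <= 0.0) return R_NegInf;
  return std::log(em);
}

// [[Rcpp::export(name = ".run_chain")]]
List run_chain(NumericMatrix X, IntegerVector outcome, NumericVector dt,
               IntegerVector plot, int n_plots,
               NumericVector beta0, NumericVector eps0, double sigma0,
               NumericVector prior_sd, double sigma_prior_sd,
               NumericVector scale_init, IntegerVector mu_cols,
               IntegerMatrix pc_cols, NumericMatrix pc_vals,
               int n_iter, int burn, int thin) {
  const int n = X.nrow(), p = X.ncol();
  if (thin < 1) stop("thin must be >= 1");
  if (burn >= n_iter) stop("burn-in must be shorter than the chain");

  // sparse column structure (period-specific columns are mostly zero)
  std::vector<std::vector<int> > nz(p);
  std::vector<std::vector<double> > nzval(p);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i)
      if (X(i, j) != 0.0) { nz[j].push_back(i); nzval[j].push_back(X(i, j)); }

  std::vector<std::vector<int> > plot_rows(std::max(n_plots, 1));
  if (n_plots > 0)
    for (int i = 0; i < n; ++i) {
      if (plot[i] < 0 || plot[i] >= n_plots) stop("plot index out of range");
      plot_rows[plot[i]].push_back(i);
    }

  std::vector<double> beta(beta0.begin(), beta0.end());
  std::vector<double> eps(n_plots, 0.0);
  for (int k = 0; k < n_plots; ++k) eps[k] = eps0[k];
  double sigma = sigma0;

  std::vector<double> eta(n, 0.0), ll(n, 0.0), scratch(n, 0.0);
  for (int j = 0; j < p; ++j)
    for (size_t t = 0; t < nz[j].size(); ++t)
      eta[nz[j][t]] += nzval[j][t] * beta[j];
  if (n_plots > 0)
    for (int i = 0; i < n; ++i) eta[i] += eps[plot[i]];
  for (int i = 0; i < n; ++i) ll[i] = ll_term(eta[i], outcome[i], dt[i]);

  std::vector<double> scale_b(scale_init.begin(), scale_init.end());
  std::vector<double> scale_e(n_plots, 0.5);
  double scale_s = 0.3, scale_r = 0.3;
  std::vector<int> acc_b(p, 0), acc_e(n_plots, 0);
  int acc_s = 0, acc_r = 0;
  const int n_pc = pc_cols.ncol();
  std::vector<double> scale_pc(n_pc, 0.3);
  std::vector<int> acc_pc(n_pc, 0);
  const int batch = 50;

  const int n_stored = (n_iter - burn) / thin;
  const int n_par = p + n_plots + (n_plots > 0 ? 1 : 0);
  NumericMatrix draws(n_stored, n_par);
  NumericMatrix loglik(n_stored, n);
  int stored = 0;

  RNGScope rng;
  for (int iter = 1; iter <= n_iter; ++iter) {
    // fixed effects, one coordinate at a time
    for (int j = 0; j < p; ++j) {
      double prop = beta[j] + scale_b[j] * norm_rand();
      double dlp = -0.5 * (prop * prop - beta[j] * beta[j]) /
                   (prior_sd[j] * prior_sd[j]);
      double d = prop - beta[j], dll = 0.0;
      const std::vector<int>& rows = nz[j];
      const std::vector<double>& vals = nzval[j];
      for (size_t t = 0; t < rows.size(); ++t) {
        int i = rows[t];
        double lt = ll_term(eta[i] + vals[t] * d, outcome[i], dt[i]);
        scratch[i] = lt;
        dll += lt - ll[i];
      }
      if (std::log(unif_rand()) < dll + dlp) {
        beta[j] = prop;
        for (size_t t = 0; t < rows.size(); ++t) {
          int i = rows[t];
          eta[i] += vals[t] * d;
          ll[i] = scratch[i];
        }
        acc_b[j]++;
      }
    }
    // plot random effects
    if (n_plots > 0) {
      double s2 = sigma * sigma;
      for (int k = 0; k < n_plots; ++k) {
        double prop = eps[k] + scale_e[k] * norm_rand();
        double dlp = (s2 > 0.0)
          ? -0.5 * (prop * prop - eps[k] * eps[k]) / s2
          : (prop == 0.0 ? 0.0 : R_NegInf);
        double d = prop - eps[k], dll = 0.0;
        const std::vector<int>& rows = plot_rows[k];
        for (size_t t = 0; t < rows.size(); ++t) {
          int i = rows[t];
          double lt = ll_term(eta[i] + d, outcome[i], dt[i]);
          scratch[i] = lt;
          dll += lt - ll[i];
        }
        if (std::log(unif_rand()) < dll + dlp) {
          eps[k] = prop;
          for (size_t t = 0; t < rows.size(); ++t) {
            int i = rows[t];
            eta[i] += d;
            ll[i] = scratch[i];
          }
          acc_e[k]++;
        }
      }
      // sigma via random walk on log(sigma); half-Normal prior + Jacobian
      {
        double ls = std::log(sigma);
        double lsp = ls + scale_s * norm_rand();
        double sp = std::exp(lsp);
        double sum_e2 = 0.0;
        for (int k = 0; k < n_plots; ++k) sum_e2 += eps[k] * eps[k];
        double cur = -0.5 * sigma * sigma / (sigma_prior_sd * sigma_prior_sd)
                     - n_plots * ls - 0.5 * sum_e2 / (sigma * sigma) + ls;
        double nw  = -0.5 * sp * sp / (sigma_prior_sd * sigma_prior_sd)
                     - n_plots * lsp - 0.5 * sum_e2 / (sp * sp) + lsp;
        if (std::log(unif_rand()) < nw - cur) { sigma = sp; acc_s++; }
      }
      // joint rescaling of all plot effects and sigma: eps' = c eps,
      // sigma' = c sigma with log c Gaussian. The eps quadratic prior
      // terms cancel; what remains is the sigma prior, the Jacobian and
      // the likelihood change. This move crosses the sigma-eps funnel.
      {
        double lc = scale_s * norm_rand();
        double c = std::exp(lc);
        double sp = sigma * c;
        double dll = 0.0;
        for (int i = 0; i < n; ++i) {
          double lt = ll_term(eta[i] + (c - 1.0) * eps[plot[i]],
                              outcome[i], dt[i]);
          scratch[i] = lt;
          dll += lt - ll[i];
        }
        double dlp = lc
          - 0.5 * (sp * sp - sigma * sigma) /
            (sigma_prior_sd * sigma_prior_sd);
        if (std::log(unif_rand()) < dll + dlp) {
          for (int k = 0; k < n_plots; ++k) eps[k] *= c;
          for (int i = 0; i < n; ++i) {
            eta[i] += (c - 1.0) * eps[plot[i]] / c;  // eps already scaled
            ll[i] = scratch[i];
          }
          sigma = sp;
        }
      }
      // recentring move: shift the period intercepts by delta and every
      // plot effect by -delta. The likelihood is invariant (each row's
      // linear predictor keeps its value), so acceptance depends on the
      // priors only; this decorrelates intercepts from plot effects.
      if (mu_cols.size() > 0) {
        double delta = scale_r * norm_rand();
        double dlp = 0.0;
        for (int t = 0; t < mu_cols.size(); ++t) {
          int j = mu_cols[t];
          double nb = beta[j] + delta;
          dlp += -0.5 * (nb * nb - beta[j] * beta[j]) /
                 (prior_sd[j] * prior_sd[j]);
        }
        double s2 = sigma * sigma;
        if (s2 > 0.0)
          for (int k = 0; k < n_plots; ++k) {
            double ne = eps[k] - delta;
            dlp += -0.5 * (ne * ne - eps[k] * eps[k]) / s2;
          }
        if (std::log(unif_rand()) < dlp) {
          for (int t = 0; t < mu_cols.size(); ++t) beta[mu_cols[t]] += delta;
          for (int k = 0; k < n_plots; ++k) eps[k] -= delta;
          acc_r++;
        }
      }
      // analogous shift moves for plot-constant covariates: adding delta
      // to all three period coefficients of covariate c while subtracting
      // delta * x_cj from every plot effect leaves each row's linear
      // predictor unchanged (plot covariates are constant over time), so
      // only the priors decide; this breaks the coefficient/plot-effect
      // confounding
      for (int c = 0; c < n_pc; ++c) {
        double delta = scale_pc[c] * norm_rand();
        double dlp = 0.0;
        for (int t = 0; t < pc_cols.nrow(); ++t) {
          int j = pc_cols(t, c);
          double nb = beta[j] + delta;
          dlp += -0.5 * (nb * nb - beta[j] * beta[j]) /
                 (prior_sd[j] * prior_sd[j]);
        }
        double s2 = sigma * sigma;
        if (s2 > 0.0)
          for (int k = 0; k < n_plots; ++k) {
            double ne = eps[k] - delta * pc_vals(k, c);
            dlp += -0.5 * (ne * ne - eps[k] * eps[k]) / s2;
          }
        if (std::log(unif_rand()) < dlp) {
          for (int t = 0; t < pc_cols.nrow(); ++t) beta[pc_cols(t, c)] += delta;
          for (int k = 0; k < n_plots; ++k) eps[k] -= delta * pc_vals(k, c);
          acc_pc[c]++;
        }
      }
    }
    // diminishing adaptation during burn-in
    if (iter <= burn && iter % batch == 0) {
      double delta = std::min(0.05, 1.0 / std::sqrt((double)(iter / batch)));
      for (int j = 0; j < p; ++j) {
        scale_b[j] *= std::exp(acc_b[j] > 0.44 * batch ? delta : -delta);
        acc_b[j] = 0;
      }
      for (int k = 0; k < n_plots; ++k) {
        scale_e[k] *= std::exp(acc_e[k] > 0.44 * batch ? delta : -delta);
        acc_e[k] = 0;
      }
      scale_s *= std::exp(acc_s > 0.44 * batch ? delta : -delta);
      acc_s = 0;
      scale_r *= std::exp(acc_r > 0.44 * batch ? delta : -delta);
      acc_r = 0;
      for (int c = 0; c < n_pc; ++c) {
        scale_pc[c] *= std::exp(acc_pc[c] > 0.44 * batch ? delta : -delta);
        acc_pc[c] = 0;
      }
    }
    // retain every thin-th draw after burn-in
    if (iter > burn && (iter - burn) % thin == 0 && stored < n_stored) {
      for (int j = 0; j < p; ++j) draws(stored, j) = beta[j];
      for (int k = 0; k < n_plots; ++k) draws(stored, p + k) = eps[k];
      if (n_plots > 0) draws(stored, p + n_plots) = sigma;
      for (int i = 0; i < n; ++i) loglik(stored, i) = ll[i];
      stored++;
    }
  }
  return List::create(_["draws"] = draws, _["loglik"] = loglik,
                      _["n_stored"] = stored);
}
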