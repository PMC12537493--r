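#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Grouped spike-and-slab ("BayesR"-style) Gibbs sampler.
//
// Model: y = sum_g X_g b_g + e,  e ~ N(0, sigma2_e I).
// Every effect b_j in group g is a priori a mixture of a Dirac spike at
// zero and K normal components N(0, gamma_k * sigma2_g); mixture
// proportions pi_g have a Dirichlet prior per group (spike-weighted by
// default, favouring sparsity), and the
// group scales sigma2_g and sigma2_e have scaled inverse-chi-square
// priors. Single-site updates condition each effect on all others (within
// and across groups). Uses R's RNG throughout so set.seed() governs
// reproducibility.
//
// X: n x p column-standardized design; group: 0-based group index per
// column; gamma: increasing positive scale constants.
//
// Returns per-kept-iteration group PVEs (Var(X_g b_g)/Var(y)), the
// residual variance fraction, and posterior means of the effects.
// [[Rcpp::export(name = ".bayesr_gibbs")]]
List bayesr_gibbs(const arma::vec& y, const arma::mat& X,
                  const arma::ivec& group, const arma::vec& gamma,
                  int n_iter, int burn_in, int thin,
                  double nu_g, double sg_frac, double nu_e,
                  double se_frac, double spike_alpha, double slab_alpha) {
  const int n = X.n_rows, p = X.n_cols;
  const int G = group.max() + 1;
  const int K = gamma.n_elem;          // slab components (spike excluded)
  const double vary = arma::var(y);

  arma::vec b(p, arma::fill::zeros);
  arma::ivec comp(p, arma::fill::zeros);  // 0 = spike, 1..K = slabs
  arma::vec xtx(p);
  for (int j = 0; j < p; ++j) xtx[j] = arma::dot(X.col(j), X.col(j));

  arma::mat u(n, G, arma::fill::zeros);   // per-group linear predictors
  arma::vec e = y;
  double sigma2_e = 0.5 * vary;
  arma::vec sigma2_g(G);
  sigma2_g.fill(0.5 * vary);
  arma::mat pi(G, K + 1);
  pi.fill(0.05 / K);
  pi.col(0).fill(0.95);

  const double S_e = se_frac * vary;
  const double S_g = sg_frac * vary;

  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  arma::mat pve(n_keep, G, arma::fill::zeros);
  arma::vec resid_frac(n_keep, arma::fill::zeros);
  arma::vec b_mean(p, arma::fill::zeros);
  arma::mat spike_count(n_keep, G, arma::fill::zeros);

  RNGScope scope;
  arma::vec logw(K + 1);
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // --- single-site effect updates ---
    for (int j = 0; j < p; ++j) {
      const int g = group[j];
      const double old_b = b[j];
      // rhs = x_j' (e + x_j old_b): regression of data-with-j-restored on x_j
      double rhs = arma::dot(X.col(j), e) + xtx[j] * old_b;
      const double base = xtx[j] * sigma2_e;
      logw[0] = std::log(pi(g, 0)) - 0.5 * rhs * rhs / base;
      for (int k = 1; k <= K; ++k) {
        const double sk2 = gamma[k - 1] * sigma2_g[g];
        const double vmarg = base + xtx[j] * xtx[j] * sk2;
        logw[k] = std::log(pi(g, k)) - 0.5 * std::log(vmarg / base)
                  - 0.5 * rhs * rhs / vmarg;
      }
      // sample the mixture component (softmax on log weights)
      const double mx = logw.max();
      double tot = 0;
      for (int k = 0; k <= K; ++k) tot += std::exp(logw[k] - mx);
      double udraw = unif_rand() * tot;
      int knew = 0;
      for (int k = 0; k <= K; ++k) {
        udraw -= std::exp(logw[k] - mx);
        if (udraw <= 0) { knew = k; break; }
      }
      double bnew = 0.0;
      if (knew > 0) {
        const double sk2 = gamma[knew - 1] * sigma2_g[g];
        const double post_var = 1.0 / (xtx[j] / sigma2_e + 1.0 / sk2);
        const double post_mean = post_var * rhs / sigma2_e;
        bnew = post_mean + std::sqrt(post_var) * norm_rand();
      }
      comp[j] = knew;
      if (bnew != old_b) {
        const double d = bnew - old_b;
        e -= X.col(j) * d;
        u.col(g) += X.col(j) * d;
        b[j] = bnew;
      }
    }

    // --- mixture proportions: Dirichlet(prior + counts) per group ---
    for (int g = 0; g < G; ++g) {
      arma::vec alpha(K + 1);
      alpha.fill(slab_alpha);
      alpha[0] = spike_alpha;
      for (int j = 0; j < p; ++j)
        if (group[j] == g) alpha[comp[j]] += 1.0;
      double s = 0;
      arma::vec draw(K + 1);
      for (int k = 0; k <= K; ++k) { draw[k] = R::rgamma(alpha[k], 1.0); s += draw[k]; }
      pi.row(g) = (draw / s).t();
    }

    // --- group scales: scaled inverse-chi-square ---
    for (int g = 0; g < G; ++g) {
      double ss = 0; int m = 0;
      for (int j = 0; j < p; ++j) {
        if (group[j] == g && comp[j] > 0) {
          ss += b[j] * b[j] / gamma[comp[j] - 1];
          ++m;
        }
      }
      sigma2_g[g] = (nu_g * S_g + ss) / R::rchisq(nu_g + m);
    }

    // --- residual variance ---
    sigma2_e = (nu_e * S_e + arma::dot(e, e)) / R::rchisq(nu_e + n);

    if (it >= burn_in && (it - burn_in) % thin == 0) {
      for (int g = 0; g < G; ++g) {
        pve(kept, g) = arma::var(u.col(g)) / vary;
        int sp = 0, tot_g = 0;
        for (int j = 0; j < p; ++j)
          if (group[j] == g) { ++tot_g; if (comp[j] == 0) ++sp; }
        spike_count(kept, g) = tot_g > 0 ? (double)sp / tot_g : 1.0;
      }
      resid_frac[kept] = arma::var(e) / vary;
      b_mean += b;
      ++kept;
    }
  }
  if (kept > 0) b_mean /= kept;

  return List::create(_["pve"] = pve.rows(0, std::max(kept - 1, 0)),
                      _["resid_frac"] = resid_frac.head(std::max(kept, 1)),
                      _["b_mean"] = b_mean,
                      _["spike_fraction"] = spike_count.rows(0, std::max(kept - 1, 0)),
                      _["n_kept"] = kept);
}
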