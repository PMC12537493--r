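#include <Rcpp.h>
using namespace Rcpp;

// Cooperative epimutation dynamics over a locus of CG sites.
//
// Each generation, every unmethylated site gains methylation with
// probability gain_base + gain_coop * (mean state of the OTHER sites),
// clamped to [0,1]; every methylated site loses methylation with
// probability loss_rate. Updates are synchronous (all sites transition
// based on the state at the start of the generation). Lineages are
// independent. Uses R's RNG so set.seed() governs reproducibility.
//
// Returns a list with the final binary state matrix (lineages x sites)
// and, optionally, the per-generation mean methylation level across all
// lineages and sites.
// [[Rcpp::export(name = ".epimutation_run")]]
List epimutation_run(int n_lineages, int n_sites, double gain_base,
                     double gain_coop, double loss_rate, int n_generations,
                     bool keep_trajectory) {
  IntegerMatrix state(n_lineages, n_sites);
  NumericVector traj(keep_trajectory ? n_generations : 0);
  const double denom = n_sites > 1 ? (double)(n_sites - 1) : 1.0;
  std::vector<int> cur(n_sites), nxt(n_sites);

  RNGScope scope;
  for (int l = 0; l < n_lineages; ++l) {
    std::fill(cur.begin(), cur.end(), 0);  // unmethylated start
    for (int g = 0; g < n_generations; ++g) {
      int tot = 0;
      for (int s = 0; s < n_sites; ++s) tot += cur[s];
      for (int s = 0; s < n_sites; ++s) {
        if (cur[s] == 1) {
          nxt[s] = (unif_rand() < loss_rate) ? 0 : 1;
        } else {
          double frac = n_sites > 1 ? (tot - cur[s]) / denom : 0.0;
          double p = gain_base + gain_coop * frac;
          if (p < 0) p = 0;
          if (p > 1) p = 1;
          nxt[s] = (unif_rand() < p) ? 1 : 0;
        }
      }
      std::swap(cur, nxt);
      if (keep_trajectory) {
        int t2 = 0;
        for (int s = 0; s < n_sites; ++s) t2 += cur[s];
        traj[g] += (double)t2 / n_sites / n_lineages;
      }
    }
    for (int s = 0; s < n_sites; ++s) state(l, s) = cur[s];
  }

  List out = List::create(_["states"] = state);
  if (keep_trajectory) out["trajectory_mean"] = traj;
  return out;
}
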