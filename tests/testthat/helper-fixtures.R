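# Small in-code fixtures shared across test files.

# site-call data.frame builder
make_sites <- function(pos, context, status) {
  data.frame(pos = pos, context = context, status = status,
             stringsAsFactors = FALSE)
}

# structured epiallele panel + trait with a causal gene chosen among
# filter-eligible markers (power-analysis design: a causal epiallele must
# be testable to be discoverable)
make_structured_study <- function(n = 600, m = 400, divergence = 0.25,
                                  causal_pve = 0.2, subpop_pve = 0.2,
                                  seed = 1) {
  sub <- rep(1:2, each = n / 2)
  E <- simulate_epialleles(n, m, subpop = sub, divergence = divergence,
                           seed = seed)
  f <- colMeans(E)
  causal <- which(f >= 0.3 & f <= 0.7)[1]
  tr <- simulate_traits(E, causal_genes = causal, causal_pve = causal_pve,
                        subpop = sub, subpop_pve = subpop_pve,
                        seed = seed + 5000L)
  list(epialleles = E, trait = tr$trait, causal = causal, subpop = sub)
}

# expand 2x2 haplotype counts (AB, Ab, aB, ab) into indicator vectors
expand_haplotypes <- function(nAB, nAb, naB, nab) {
  list(a = rep(c(1, 1, 0, 0), c(nAB, nAb, naB, nab)),
       b = rep(c(1, 0, 1, 0), c(nAB, nAb, naB, nab)))
}
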