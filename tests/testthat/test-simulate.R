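# Synthetic-data generators: determinism, degenerate limits, target
# recovery, and the cooperative epimutation model against an exact
# Markov-chain oracle.

test_that("every generator is bit-identical under a fixed seed", {
  cfg <- epimutation_config(n_sites = 4, gain_base = 0.02, gain_coop = 0.1,
                            loss_rate = 0.05, n_generations = 200,
                            n_lineages = 50, seed = 3)
  expect_identical(simulate_epimutation_population(cfg)$states,
                   simulate_epimutation_population(cfg)$states)

  pcfg <- population_sim_config(n_accessions = 80, n_snps = 60,
                                n_subpopulations = 2, divergence = 0.2,
                                seed = 9)
  expect_identical(simulate_genotypes(pcfg)$genotypes,
                   simulate_genotypes(pcfg)$genotypes)

  E <- simulate_epialleles(40, 30, seed = 4)
  expect_identical(E, simulate_epialleles(40, 30, seed = 4))

  st <- data.frame(chrom = "Chr1", pos = 1:100, strand = "+",
                   context = "CG", accession = "a1",
                   state = rep(c(0L, 1L), 50))
  rcfg <- read_sim_config(mean_depth = 20, seed = 11)
  expect_identical(simulate_reads(st, rcfg), simulate_reads(st, rcfg))

  tr1 <- simulate_traits(E, causal_genes = 2, causal_pve = 0.3, seed = 6)
  tr2 <- simulate_traits(E, causal_genes = 2, causal_pve = 0.3, seed = 6)
  expect_identical(tr1$trait, tr2$trait)
})

test_that("epimutation config validates probabilities and counts", {
  expect_error(epimutation_config(gain_base = -0.1), "probabilities")
  expect_error(epimutation_config(loss_rate = 1.2), "probabilities")
  expect_error(epimutation_config(n_generations = 0), ">= 1")
})

test_that("no gain process means methylation never appears", {
  cfg <- epimutation_config(n_sites = 5, gain_base = 0, gain_coop = 0,
                            loss_rate = 0.1, n_generations = 300,
                            n_lineages = 30, seed = 1)
  out <- simulate_epimutation_population(cfg, keep_trajectory = TRUE)
  expect_true(all(out$levels == 0))
  expect_true(all(out$trajectory_mean == 0))
})

test_that("without loss the fully methylated state is absorbing", {
  cfg <- epimutation_config(n_sites = 5, gain_base = 0.01, gain_coop = 0,
                            loss_rate = 0, n_generations = 5000,
                            n_lineages = 60, seed = 2)
  expect_gt(mean(simulate_epimutation_population(cfg)$levels), 0.99)
})

test_that("2-site epimutation chain matches its exact stationary vector", {
  gb <- 0.03; gc <- 0.25; lr <- 0.06
  # oracle: enumerate the 4 states and build the transition matrix from
  # the model definition (synchronous update, other-site mean coupling)
  states <- as.matrix(expand.grid(0:1, 0:1))
  P <- matrix(0, 4, 4)
  for (i in 1:4) {
    s <- states[i, ]
    pr1 <- vapply(1:2, function(k) {
      if (s[k] == 1) 1 - lr else min(1, gb + gc * s[-k])
    }, 0)
    for (j in 1:4)
      P[i, j] <- prod(ifelse(states[j, ] == 1, pr1, 1 - pr1))
  }
  ev <- eigen(t(P))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- stat / sum(stat)

  cfg <- epimutation_config(n_sites = 2, gain_base = gb, gain_coop = gc,
                            loss_rate = lr, n_generations = 4000,
                            n_lineages = 3000, seed = 17)
  sim <- simulate_epimutation_population(cfg)
  emp <- tabulate(sim$states %*% c(1, 2) + 1, 4) / cfg$n_lineages
  expect_lt(0.5 * sum(abs(emp - stat)), 0.03)
})

test_that("cooperative gain produces a bimodal population of gbM levels", {
  cfg <- epimutation_config(n_sites = 10, gain_base = 2e-5,
                            gain_coop = 0.3, loss_rate = 0.05,
                            n_generations = 5000, n_lineages = 1500,
                            seed = 5)
  lv <- simulate_epimutation_population(cfg)$levels
  # modes at the extremes, thin middle
  lo <- mean(lv <= 0.2); mid <- mean(lv > 0.3 & lv < 0.7)
  hi <- mean(lv >= 0.8)
  expect_gt(lo, mid)
  expect_gt(hi, mid)
  expect_gt(lo + hi, 0.6)
})

test_that("stronger cooperative occupancy raises methylated-class frequency", {
  freq_of <- function(coop) {
    cfg <- epimutation_config(n_sites = 8, gain_base = 2e-5,
                              gain_coop = coop, loss_rate = 0.05,
                              n_generations = 8000, n_lineages = 800,
                              seed = 21)
    mean(simulate_epimutation_population(cfg)$levels > 0.5)
  }
  expect_gt(freq_of(0.35), freq_of(0.2))
})

test_that("divergent subpopulations separate on the leading PC", {
  pcfg <- population_sim_config(n_accessions = 200, n_snps = 400,
                                n_subpopulations = 2, divergence = 0.3,
                                seed = 8)
  g <- simulate_genotypes(pcfg)
  pc1 <- prcomp(g$genotypes)$x[, 1]
  assign <- (pc1 > median(pc1)) + 1
  acc <- max(mean(assign == g$subpop), mean(assign != g$subpop))
  expect_gt(acc, 0.95)
})

test_that("panmictic halves differ only by sampling noise in frequency", {
  pcfg <- population_sim_config(n_accessions = 400, n_snps = 300,
                                n_subpopulations = 1, divergence = 0,
                                seed = 12)
  G <- simulate_genotypes(pcfg)$genotypes
  d <- abs(colMeans(G[1:200, ]) - colMeans(G[201:400, ]))
  # binomial sampling sd of a frequency difference is ~ sqrt(2 p q / 200)
  expect_lt(mean(d), 3 * sqrt(2 * 0.25 / 200))
})

test_that("within-block LD decays with distance", {
  pcfg <- population_sim_config(n_accessions = 500, n_snps = 40,
                                ld_block_size = 20, ld_rho = 0.8, seed = 3)
  G <- simulate_genotypes(pcfg)$genotypes
  r_adjacent <- abs(cor(G[, 1], G[, 2]))
  r_far <- abs(cor(G[, 1], G[, 15]))
  expect_gt(r_adjacent, r_far)
})

test_that("expression simulation hits target variance fractions", {
  n <- 1000
  Xs <- list(gbm = simulate_epialleles(n, 80, seed = 1),
             tem = simulate_epialleles(n, 40, seed = 2),
             snp = simulate_genotypes(
               population_sim_config(n_accessions = n, n_snps = 150,
                                     seed = 3))$genotypes)
  tg <- c(gbm = 0.15, tem = 0.25, snp = 0.25)
  sim <- simulate_expression(Xs, tg, n_genes = 5, seed = 4)
  for (t in sim$truth)
    expect_true(all(abs(unlist(t$realized) - tg) < 0.03))

  # zero targets: pure noise at the declared residual variance
  sim0 <- simulate_expression(Xs, c(gbm = 0, tem = 0, snp = 0),
                              n_genes = 3, seed = 5)
  v <- apply(sim0$expression, 1, var)
  expect_true(all(abs(v - 1) < 0.1))

  # single causal marker, zero noise: perfect collinearity
  sim1 <- simulate_expression(Xs["snp"], c(snp = 1), n_genes = 1,
                              n_causal = c(snp = 1L), seed = 6)
  idx <- sim1$truth[[1]]$groups$snp$idx
  expect_equal(abs(cor(sim1$expression[1, ], Xs$snp[, idx])), 1,
               tolerance = 1e-12)
})

test_that("expression simulation rejects mismatched axes and bad targets", {
  Xs <- list(gbm = simulate_epialleles(50, 10, seed = 1),
             snp = simulate_epialleles(60, 10, seed = 2))
  expect_error(simulate_expression(Xs, c(gbm = 0.2, snp = 0.2)),
               "accession axis")
  expect_error(
    simulate_expression(Xs["gbm"], c(gbm = 1.2)), "sum to <= 1")
})

test_that("read simulation reproduces the conversion error model", {
  st <- data.frame(chrom = "Chr1", pos = seq_len(20000), strand = "+",
                   context = "CG", accession = "a1", state = 0L)
  rc <- read_sim_config(mean_depth = 10, nonconversion_rate = 0.005,
                        overconversion_rate = 0, seed = 2)
  tab <- simulate_reads(st, rc)
  frac <- sum(tab$reads_meth) / sum(tab$reads_total)
  expect_gt(frac, 0.004); expect_lt(frac, 0.006)

  # no error: methylated fraction equals the true state in expectation
  st$state <- rep(c(0L, 1L), each = 10000)
  rc0 <- read_sim_config(mean_depth = 30, nonconversion_rate = 1e-12,
                         overconversion_rate = 1e-12, seed = 3)
  tab0 <- simulate_reads(st, rc0)
  expect_equal(sum(tab0$reads_meth[st$state == 0]), 0)
  expect_equal(sum(tab0$reads_meth[st$state == 1]),
               sum(tab0$reads_total[st$state == 1]))
})

test_that("trait simulation validates axes and records truth", {
  E <- simulate_epialleles(100, 20, seed = 1)
  G <- simulate_epialleles(90, 20, seed = 2)
  expect_error(simulate_traits(E, genotypes = G), "accession axis")
  tr <- simulate_traits(E, causal_genes = c(3, 7), causal_pve = 0.4,
                        seed = 3)
  expect_identical(tr$truth$causal_genes, c(3, 7))
  expect_length(tr$trait, 100)
})
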