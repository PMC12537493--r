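#!/usr/bin/env Rscript
# Decide which methylation-expression associations survive accounting for
# genetic variation: cis scans, nested populations, haplogroups, LD and
# trans-QTL variance (including the small-panel Beavis inflation).

library(epiqtl)

seed <- 20260105L
out <- "results/confound"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## verdicts over a mixed cohort of genes -----------------------------------
set.seed(child_seed(seed, 1))
n <- 600
rows <- list()
for (i in 1:100) {
  G <- simulate_genotypes(population_sim_config(
    n_accessions = n, n_snps = 30,
    seed = child_seed(seed, 100 + i)))$genotypes
  epigenetic <- i <= 50
  if (epigenetic) {
    mcg <- runif(n)
    expr <- sqrt(0.15) * scale(mcg)[, 1] + sqrt(0.85) * rnorm(n)
  } else {
    snp <- G[, 15]
    mcg <- pmin(1, pmax(0, 0.3 * snp + 0.25 + 0.05 * rnorm(n)))
    expr <- sqrt(0.3) * scale(snp)[, 1] + sqrt(0.7) * rnorm(n)
  }
  v <- confound_verdict(mcg, expr, G)
  rows[[i]] <- data.frame(gene = sprintf("gene%03d", i),
                          truth = ifelse(epigenetic, "retained", "lost"),
                          verdict = v$final_class,
                          colocalized = v$colocalized_snp)
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out, "verdicts.csv"), row.names = FALSE)
cat(sprintf("verdict accuracy on known truth: %.1f%% of %d genes\n",
            100 * mean(tab$verdict == tab$truth), nrow(tab)))

## haplogroups on a realistic LD panel --------------------------------------
Gw <- simulate_genotypes(population_sim_config(
  n_accessions = 600, n_snps = 8, ld_block_size = 8, ld_rho = 0.95,
  maf_range = c(0.05, 0.3), seed = child_seed(seed, 2)))$genotypes
hg <- define_haplogroups(Gw, min_size = 15)
cat(sprintf("haplogroups in an 8-SNP window: %d kept (>=15 members), %d discarded\n",
            length(hg), length(attr(hg, "discarded"))))
set.seed(child_seed(seed, 3))
meth <- setNames(rbinom(600, 1, 0.5), rownames(Gw))
trait <- setNames(0.8 * meth + rnorm(600), rownames(Gw))
wha <- within_haplogroup_association(hg, meth, trait)
write.csv(wha, file.path(out, "within_haplogroup.csv"), row.names = FALSE)
cat(sprintf("methylation effect significant (p < 0.05) in %d/%d testable haplogroups\n",
            sum(wha$p_value < 0.05), nrow(wha)))

## LD between an epiallele and a linked SNP --------------------------------
set.seed(child_seed(seed, 4))
snp <- rbinom(600, 1, 0.5)
epi <- ifelse(runif(600) < 0.85, snp, rbinom(600, 1, 0.5))
ld <- ld_epiallele_snp(epi, snp)
cat(sprintf("epiallele-SNP LD: r = %.3f, D' = %.3f, p = %.2g\n",
            ld$r, ld$D_prime, ld$p_value))

## Beavis effect: trans-PVE in small vs full panels ------------------------
G <- simulate_genotypes(population_sim_config(
  n_accessions = 625, n_snps = 1000, seed = child_seed(seed, 5)))$genotypes
set.seed(child_seed(seed, 6))
pves <- runif(30, 0.02, 0.15)
snp_idx <- sample(1000, 30)
idx133 <- sample(625, 133)
full <- c(); small <- c()
for (g in 1:30) {
  mcg <- sqrt(pves[g]) * scale(G[, snp_idx[g]])[, 1] +
    sqrt(1 - pves[g]) * rnorm(625)
  f <- trans_pve(mcg, G)
  sm <- trans_pve(mcg[idx133], G[idx133, ])
  if (f$n_significant > 0) full <- c(full, f$percent)
  if (sm$n_significant > 0) small <- c(small, sm$percent)
}
cat(sprintf("mean trans-PVE among significant hits: %.1f%% at n=625 (%d hits) vs %.1f%% at n=133 (%d hits)\n",
            mean(full), length(full), mean(small), length(small)))
write.csv(data.frame(panel = c("full_625", "small_133"),
                     mean_trans_pve = c(mean(full), mean(small)),
                     n_hits = c(length(full), length(small))),
          file.path(out, "beavis.csv"), row.names = FALSE)
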